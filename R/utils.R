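#' @keywords internal
"_PACKAGE"

# Stage seeds are drawn once from the global seed so that toggling one stage
# never shifts another stage's randomness.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max %/% 2L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# md5 of a canonical JSON rendering, used to stamp manifests.
object_hash <- function(obj) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}

# Fixed-precision numeric formatting so repeated runs write byte-identical
# artifacts.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(v, digits = 17, trim = TRUE, scientific = TRUE)
  }, character(1))
  out
}

write_stage_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default adjustment covariate set
#'
#' The covariates used throughout the matched analyses: recruitment center
#' (a matching variable, retained so its within-stratum constancy is detected
#' and logged), age, sex, smoking (3 categories), BMI, type 2 diabetes,
#' hypertension, family history of coronary heart disease, leisure-time
#' physical activity, education (3 categories), statin use, and intervention
#' arm (3 groups).
#'
#' @return Character vector of covariate names in the subject table.
#' @export
default_covariates <- function() {
  c("center", "age", "sex", "smoking", "bmi", "diabetes", "hypertension",
    "family_history", "physical_activity", "education", "statin",
    "intervention")
}

#' Build the covariate design matrix from a subject table
#'
#' Continuous and binary covariates enter as single columns; 3-category
#' covariates (smoking, education, intervention) and center enter as
#' treatment-coded indicator sets.
#'
#' @param subjects Subject data frame (see [generate_cohort()]).
#' @param covariates Character vector of covariate names; default
#'   [default_covariates()].
#' @return Numeric design matrix with one row per subject.
#' @export
covariate_design <- function(subjects, covariates = default_covariates()) {
  cols <- list()
  for (cv in covariates) {
    if (!cv %in% names(subjects)) stop("unknown covariate: ", cv)
    v <- subjects[[cv]]
    if (cv %in% c("smoking", "education", "intervention", "center") ||
        is.factor(v) || is.character(v)) {
      f <- factor(v)
      if (nlevels(f) < 2) {
        m <- matrix(as.numeric(f == levels(f)[1]), ncol = 1,
                    dimnames = list(NULL, paste0(cv, levels(f)[1])))
      } else {
        m <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(m) <- paste0(cv, levels(f)[-1])
      }
      cols[[cv]] <- m
    } else {
      cols[[cv]] <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cv))
    }
  }
  do.call(cbind, cols)
}
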