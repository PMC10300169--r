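#' Specify a synthetic matched case-control lipidomics cohort
#'
#' Defines the generating conditions for [generate_cohort()]: the matched
#' design (1 case : 1-3 controls per stratum, matched on center, sex and age
#' within +/- 5 years), a block-correlated lipid panel whose blocks play the
#' role of lipid-class clusters, sparse true log-odds effects acting on the
#' standardized (latent normal) lipid scale, optional covariate effects, and
#' left-censored missingness mimicking below-detection-limit values.
#'
#' Default sizes emulate a nested case-control sample of roughly 1250
#' subjects: 512 strata with a 1/2/3-control mix averaging ~1.43 controls per
#' case, and a panel of 216 lipid features in 18 correlation blocks.
#'
#' @param n_strata Number of matched strata (one case each).
#' @param controls_per_case Either a single integer in 1..3 (fixed stratum
#'   size) or a length-3 probability vector over 1, 2 and 3 controls.
#' @param n_lipids Number of lipid features.
#' @param n_clusters Number of correlation blocks (contiguous, near-equal).
#' @param within_cluster_rho Exchangeable correlation inside a block, in
#'   `[0, 1)`.
#' @param between_cluster_rho Correlation between features of different
#'   blocks (default 0).
#' @param true_effects Named numeric vector of log-odds per SD on the latent
#'   standardized lipid scale; names are feature indices (e.g. `"7"`) or
#'   feature labels (e.g. `"lipid_007"`).
#' @param covariate_effects Named numeric vector of log-odds per unit for
#'   numeric/binary subject covariates (age, bmi, physical_activity,
#'   diabetes, hypertension, family_history, statin).
#' @param missing_rate Fraction of each feature set missing, in `[0, 0.2]`.
#' @param censor_mode `"left_censor"` (lowest values go missing, the
#'   assumption under half-minimum imputation) or `"MCAR"`.
#' @param reuse_controls Allow a control's profile to be reused across
#'   strata, mimicking incidence-density sampling with replacement. Off by
#'   default to keep variance-estimation assumptions simple.
#' @param reuse_rate Probability a control slot reuses a compatible earlier
#'   control when `reuse_controls` is `TRUE`.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_strata = 512,
                        controls_per_case = c(0.62, 0.33, 0.05),
                        n_lipids = 216,
                        n_clusters = 18,
                        within_cluster_rho = 0.5,
                        between_cluster_rho = 0,
                        true_effects = numeric(0),
                        covariate_effects = numeric(0),
                        missing_rate = 0.05,
                        censor_mode = c("left_censor", "MCAR"),
                        reuse_controls = FALSE,
                        reuse_rate = 0.1,
                        seed = 1L) {
  censor_mode <- match.arg(censor_mode)
  spec <- structure(list(
    n_strata = as.integer(n_strata),
    controls_per_case = controls_per_case,
    n_lipids = as.integer(n_lipids),
    n_clusters = as.integer(n_clusters),
    within_cluster_rho = within_cluster_rho,
    between_cluster_rho = between_cluster_rho,
    true_effects = true_effects,
    covariate_effects = covariate_effects,
    missing_rate = missing_rate,
    censor_mode = censor_mode,
    reuse_controls = isTRUE(reuse_controls),
    reuse_rate = reuse_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_strata < 1) stop("n_strata must be >= 1")
    if (length(controls_per_case) == 1) {
      if (!controls_per_case %in% 1:3) stop("controls_per_case must be in {1,2,3}")
    } else if (length(controls_per_case) == 3) {
      if (any(controls_per_case < 0) || sum(controls_per_case) <= 0)
        stop("controls_per_case probabilities must be nonnegative and sum > 0")
    } else stop("controls_per_case: scalar in {1,2,3} or length-3 probabilities")
    if (n_lipids < n_clusters || n_clusters < 1)
      stop("need n_lipids >= n_clusters >= 1")
    if (within_cluster_rho < 0 || within_cluster_rho >= 1)
      stop("within_cluster_rho must be in [0, 1)")
    if (missing_rate < 0 || missing_rate > 0.2)
      stop("missing_rate must be in [0, 0.2]")
  })
  eff <- resolve_effects(spec$true_effects, spec$n_lipids)
  if (any(is.na(eff$idx)))
    stop("true_effects names must be feature indices or lipid_### labels")
  bad <- setdiff(names(spec$covariate_effects),
                 c("age", "bmi", "physical_activity", "diabetes",
                   "hypertension", "family_history", "statin"))
  if (length(bad)) stop("covariate_effects: unsupported covariate(s) ",
                        paste(bad, collapse = ", "))
  # correlation spec must give a positive-definite block matrix
  sig <- try(chol(block_sigma(spec)), silent = TRUE)
  if (inherits(sig, "try-error"))
    stop("correlation specification is not positive definite (within_cluster_rho = ",
         spec$within_cluster_rho, ", between_cluster_rho = ",
         spec$between_cluster_rho, ")")
  invisible(spec)
}

resolve_effects <- function(true_effects, n_lipids) {
  if (!length(true_effects)) return(list(idx = integer(0), beta = numeric(0)))
  nm <- names(true_effects)
  if (is.null(nm)) stop("true_effects must be named")
  idx <- suppressWarnings(as.integer(nm))
  lab <- grepl("^lipid_", nm)
  idx[lab] <- suppressWarnings(as.integer(sub("^lipid_", "", nm[lab])))
  idx[!is.na(idx) & (idx < 1 | idx > n_lipids)] <- NA_integer_
  list(idx = idx, beta = unname(true_effects))
}

cluster_blocks <- function(n_lipids, n_clusters) {
  sizes <- rep(n_lipids %/% n_clusters, n_clusters)
  extra <- n_lipids %% n_clusters
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_clusters), sizes)
}

block_sigma <- function(spec) {
  cl <- cluster_blocks(spec$n_lipids, spec$n_clusters)
  same <- outer(cl, cl, "==")
  sig <- matrix(spec$between_cluster_rho, spec$n_lipids, spec$n_lipids)
  sig[same] <- spec$within_cluster_rho
  diag(sig) <- 1
  sig
}

#' Generate a matched case-control cohort with known ground truth
#'
#' Lipid abundances are log-normal: a block-correlated multivariate normal
#' latent matrix is exponentiated to the abundance scale. Case status is
#' assigned within each stratum by sampling one member with probability
#' proportional to `exp(linear predictor)` -- the exact data-generating
#' assumption of conditional logistic regression, so recovered coefficients
#' can be compared directly to the spec's `true_effects`. Missingness is then
#' applied per feature (`left_censor` removes the lowest `missing_rate`
#' quantile, emulating below-detection-limit censoring).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `matched_cohort`: `subjects` (subject table),
#'   `lipids` (subjects x features abundance matrix with `NA` for missing),
#'   `feature_names`, and `truth` (cluster labels, effect map, the SD of the
#'   generating composite linear predictor, reuse count, seed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)

  G <- spec$n_strata
  n_ctrl <- if (length(spec$controls_per_case) == 1) {
    rep(as.integer(spec$controls_per_case), G)
  } else {
    sample(1:3, G, replace = TRUE,
           prob = spec$controls_per_case / sum(spec$controls_per_case))
  }
  sizes <- 1L + n_ctrl
  n <- sum(sizes)
  stratum_id <- rep(seq_len(G), sizes)

  centers <- sprintf("C%02d", 1:10)
  st_center <- sample(centers, G, replace = TRUE)
  st_sex <- sample(c("male", "female"), G, replace = TRUE)
  st_age <- pmin(78, pmax(57, stats::rnorm(G, 68.5, 5.8)))

  subjects <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    stratum_id = stratum_id,
    is_case = 0L,
    center = st_center[stratum_id],
    age = round(st_age[stratum_id] + stats::runif(n, -2.5, 2.5), 1),
    sex = st_sex[stratum_id],
    bmi = round(stats::rnorm(n, 30, 3.8), 1),
    smoking = sample(c("never", "current", "former"), n, TRUE,
                     prob = c(0.58, 0.135, 0.285)),
    diabetes = stats::rbinom(n, 1, 0.49),
    hypertension = stats::rbinom(n, 1, 0.84),
    family_history = stats::rbinom(n, 1, 0.19),
    physical_activity = round(stats::rgamma(n, shape = 1.1, scale = 207), 1),
    education = sample(c("primary", "secondary", "college"), n, TRUE,
                       prob = c(0.78, 0.16, 0.06)),
    statin = stats::rbinom(n, 1, 0.36),
    intervention = sample(c("control", "evoo", "nuts"), n, TRUE),
    stringsAsFactors = FALSE
  )

  p <- spec$n_lipids
  cl <- cluster_blocks(p, spec$n_clusters)
  sigma <- block_sigma(spec)
  L <- chol(sigma)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% L
  feature_names <- sprintf("lipid_%03d", seq_len(p))
  colnames(Z) <- feature_names

  n_reused <- 0L
  if (spec$reuse_controls && G > 1) {
    is_ctrl_slot <- seq_len(n)  # cases not yet assigned; reuse any member slot but the first
    first_of_stratum <- !duplicated(stratum_id)
    for (i in which(!first_of_stratum & stratum_id > 1)) {
      if (stats::runif(1) < spec$reuse_rate) {
        compatible <- which(stratum_id < stratum_id[i] &
                              subjects$sex == subjects$sex[i] &
                              subjects$center == subjects$center[i] &
                              abs(subjects$age - st_age[stratum_id[i]]) <= 2)
        if (length(compatible)) {
          src <- compatible[sample.int(length(compatible), 1)]
          keep_id <- subjects$subject_id[i]
          keep_str <- subjects$stratum_id[i]
          subjects[i, ] <- subjects[src, ]
          subjects$subject_id[i] <- keep_id
          subjects$stratum_id[i] <- keep_str
          Z[i, ] <- Z[src, ]
          n_reused <- n_reused + 1L
        }
      }
    }
  }

  eff <- resolve_effects(spec$true_effects, p)
  beta <- numeric(p)
  beta[eff$idx] <- beta[eff$idx] + eff$beta
  lp <- drop(Z %*% beta)
  for (nm in names(spec$covariate_effects)) {
    lp <- lp + spec$covariate_effects[[nm]] * as.numeric(subjects[[nm]])
  }
  # conditional-logit case assignment within each stratum
  for (g in seq_len(G)) {
    rows <- which(stratum_id == g)
    lg <- lp[rows] - max(lp[rows])
    case <- rows[sample.int(length(rows), 1, prob = exp(lg))]
    subjects$is_case[case] <- 1L
  }

  mu <- stats::rnorm(p, 2, 1)
  abund <- exp(sweep(Z, 2, mu, "+"))

  if (spec$missing_rate > 0) {
    k <- floor(spec$missing_rate * n)
    if (k > 0) {
      for (j in seq_len(p)) {
        miss <- if (spec$censor_mode == "left_censor") {
          order(abund[, j])[seq_len(k)]
        } else {
          sample.int(n, k)
        }
        abund[miss, j] <- NA_real_
      }
    }
  }
  rownames(abund) <- subjects$subject_id

  truth <- list(
    clusters = stats::setNames(cl, feature_names),
    effects = stats::setNames(beta[beta != 0],
                              feature_names[which(beta != 0)]),
    composite_sd = sqrt(drop(t(beta) %*% sigma %*% beta)),
    n_reused_controls = n_reused,
    seed = spec$seed
  )
  structure(list(subjects = subjects, lipids = abund,
                 feature_names = feature_names, truth = truth, spec = spec),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("matched_cohort:", nrow(x$subjects), "subjects in",
      length(unique(x$subjects$stratum_id)), "strata;",
      length(x$feature_names), "lipid features;",
      sum(x$subjects$is_case), "cases\n")
  if (!is.null(x$truth))
    cat("  ground truth:", length(x$truth$effects), "true effects,",
        max(x$truth$clusters), "generating blocks\n")
  invisible(x)
}

#' Validate the matched-design invariants of a cohort
#'
#' Checks unique subject ids, 1-case / 1-3-control stratum composition,
#' shared sex and center within strata, age span at most 5 years, and
#' alignment between the subject table and the lipid matrix. Errors carry
#' row-level diagnostics naming the offending stratum or subject.
#'
#' @param cohort A `matched_cohort`.
#' @return The cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  s <- cohort$subjects
  dup <- s$subject_id[duplicated(s$subject_id)]
  if (length(dup)) stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  if (!identical(rownames(cohort$lipids), s$subject_id))
    stop("lipid matrix row order does not match the subject table")
  if (!identical(colnames(cohort$lipids), cohort$feature_names))
    stop("lipid matrix columns do not match feature_names")
  if (any(cohort$lipids < 0, na.rm = TRUE))
    stop("negative lipid abundances")
  for (g in split(seq_len(nrow(s)), s$stratum_id)) {
    sid <- s$stratum_id[g[1]]
    nc <- sum(s$is_case[g])
    if (nc != 1L)
      stop("stratum ", sid, " has ", nc, " cases (expected exactly 1)")
    if (length(g) < 2L || length(g) > 4L)
      stop("stratum ", sid, " has ", length(g) - 1L,
           " controls (expected 1-3)")
    if (length(unique(s$sex[g])) != 1L)
      stop("stratum ", sid, " mixes sexes")
    if (length(unique(s$center[g])) != 1L)
      stop("stratum ", sid, " mixes centers")
    if (diff(range(s$age[g])) > 5)
      stop("stratum ", sid, " age span exceeds 5 years")
  }
  invisible(cohort)
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` emits `subjects.csv`, `lipids.csv` (subject_id + one
#' column per feature; empty cell or `NA` = missing), an optional
#' `truth.json` ground-truth sidecar (so real-data runs are indistinguishable
#' from synthetic ones when the sidecar is absent), and `manifest.json` with
#' the seed and a hash of the generating spec. `read_cohort()` round-trips
#' them and re-validates the matched-design invariants.
#'
#' @param cohort A `matched_cohort`.
#' @param dir Directory to write into (created if needed).
#' @return `write_cohort()`: the directory, invisibly. `read_cohort()`: a
#'   `matched_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  lip <- data.frame(subject_id = rownames(cohort$lipids),
                    cohort$lipids, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in 2:ncol(lip)) lip[[j]] <- fmt_num(lip[[j]])
  utils::write.csv(lip, file.path(dir, "lipids.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    tr$clusters <- as.list(tr$clusters)  # keep names through JSON
    tr$effects <- as.list(tr$effects)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    seed = if (!is.null(cohort$spec)) cohort$spec$seed else NA,
    spec_hash = if (!is.null(cohort$spec)) object_hash(unclass(cohort$spec)) else NA,
    n_subjects = nrow(cohort$subjects),
    n_strata = length(unique(cohort$subjects$stratum_id)),
    n_features = length(cohort$feature_names)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE,
                              na.strings = c("", "NA"))
  required <- c("subject_id", "stratum_id", "is_case", "center", "age",
                "sex", "bmi", "smoking", "diabetes", "hypertension",
                "family_history", "physical_activity", "education",
                "statin", "intervention")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols))
    stop("subjects.csv is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  lip <- utils::read.csv(file.path(dir, "lipids.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("", "NA"))
  if (names(lip)[1] != "subject_id") stop("lipids.csv must start with subject_id")
  m <- as.matrix(lip[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- lip$subject_id
  if (!identical(lip$subject_id, subjects$subject_id))
    stop("lipids.csv subject order differs from subjects.csv")
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth$clusters <- unlist(truth$clusters)
    truth$effects <- unlist(truth$effects)
  }
  cohort <- structure(list(subjects = subjects, lipids = m,
                           feature_names = colnames(m), truth = truth,
                           spec = NULL),
                      class = "matched_cohort")
  validate_cohort(cohort)
  cohort
}
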