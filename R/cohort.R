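# Synthetic cohort simulator. Emulates the structure of a population-based
# cardiometabolic cohort: a participant-by-feature table mixing continuous
# clinical variables, integer-coded categorical clinical variables, and a
# large right-skewed (log-normal) metabolite panel, with a rare binary
# outcome generated from a logistic model on a sparse set of signal
# features. The defaults reproduce the study schema the package targets:
# 1376 non-cases, 78 incident cases, 19 clinical variables, 363 metabolites.

.default_clinical_continuous <- c(
  "age", "bmi", "waist_hip_ratio", "systolic_bp", "diastolic_bp",
  "total_chol", "hdl_chol", "ldl_chol", "hba1c", "fasting_glucose",
  "alcohol", "hs_crp")
.default_clinical_categorical <- c(
  sex = 2, smoker = 2, physical_activity = 4, glucose_tolerance = 3,
  fasting = 2, stroke = 2, statin = 2)

#' Specification of a synthetic cohort
#'
#' Collects every parameter of the cohort simulator. The defaults replicate
#' the target study schema: 1376 negatives, 78 positives, 12 continuous plus
#' 7 categorical clinical variables (382 features total with the 363
#' metabolites), metabolites log-normal, and the outcome driven by sex,
#' glucose-tolerance group, physical activity and a sparse metabolite
#' subset.
#'
#' @param n_negative,n_positive class counts (exact in the output).
#' @param n_clinical_continuous,n_clinical_categorical clinical feature counts.
#' @param categorical_level_counts integer vector (length
#'   `n_clinical_categorical`) of level counts, each >= 2.
#' @param n_metabolites metabolite panel width.
#' @param signal_features two-column matrix (or data.frame) with columns
#'   `index` (feature column index) and `beta` (log-odds coefficient).
#'   Clinical features contribute their stored value to the linear
#'   predictor; metabolite features contribute their z-scored log value.
#' @param metabolite_log_mean,metabolite_log_sd per-metabolite location and
#'   scale on the log scale (recycled).
#' @param missing_col_rate,missing_row_rate MCAR missingness rates used by
#'   [inject_missingness()].
#' @param n_missing_cols,n_missing_rows how many metabolite columns / rows
#'   are designated to receive missingness.
#' @param seed integer seed giving byte-identical cohorts.
#' @return an object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [inject_missingness()]
#' @export
cohort_spec <- function(n_negative = 1376, n_positive = 78,
                        n_clinical_continuous = 12,
                        n_clinical_categorical = 7,
                        categorical_level_counts = NULL,
                        n_metabolites = 363,
                        signal_features = NULL,
                        metabolite_log_mean = 0, metabolite_log_sd = 1,
                        missing_col_rate = 0, missing_row_rate = 0,
                        n_missing_cols = 0, n_missing_rows = 0,
                        seed = 1L) {
  if (is.null(categorical_level_counts)) {
    categorical_level_counts <-
      if (n_clinical_categorical == length(.default_clinical_categorical))
        unname(.default_clinical_categorical)
      else rep(2L, n_clinical_categorical)
  }
  p <- n_clinical_continuous + n_clinical_categorical + n_metabolites
  if (is.null(signal_features)) signal_features <- default_signal_features(
    n_clinical_continuous, n_clinical_categorical, categorical_level_counts,
    n_metabolites)
  signal_features <- as.data.frame(signal_features)
  if (nrow(signal_features) > 0) {
    names(signal_features) <- c("index", "beta")[seq_len(ncol(signal_features))]
  } else {
    signal_features <- data.frame(index = integer(), beta = numeric())
  }
  spec <- structure(list(
    n_negative = as.integer(n_negative), n_positive = as.integer(n_positive),
    n_clinical_continuous = as.integer(n_clinical_continuous),
    n_clinical_categorical = as.integer(n_clinical_categorical),
    categorical_level_counts = as.integer(categorical_level_counts),
    n_metabolites = as.integer(n_metabolites),
    signal_features = signal_features,
    metabolite_log_mean = rep_len(metabolite_log_mean, n_metabolites),
    metabolite_log_sd = rep_len(metabolite_log_sd, n_metabolites),
    missing_col_rate = missing_col_rate, missing_row_rate = missing_row_rate,
    n_missing_cols = as.integer(n_missing_cols),
    n_missing_rows = as.integer(n_missing_rows),
    seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

# Default planted signal: male sex, worse glucose tolerance, lower physical
# activity, and 8 metabolites with alternating-sign effects.
default_signal_features <- function(n_cont, n_cat, levels, n_met) {
  sig <- data.frame(index = integer(), beta = numeric())
  cat_names <- names(.default_clinical_categorical)
  if (n_cat == length(cat_names)) {
    idx <- function(nm) n_cont + match(nm, cat_names)
    sig <- rbind(sig,
      data.frame(index = idx("sex"), beta = 1.0),
      data.frame(index = idx("glucose_tolerance"), beta = 0.5),
      data.frame(index = idx("physical_activity"), beta = 0.35))
  }
  if (n_met >= 8) {
    met_idx <- n_cont + n_cat + round(seq(1, n_met, length.out = 8))
    sig <- rbind(sig, data.frame(index = met_idx,
                                 beta = rep(c(0.5, -0.5), 4)))
  }
  sig
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (any(c(n_negative, n_positive, n_clinical_continuous,
              n_clinical_categorical, n_metabolites) < 0))
      stop("cohort_spec counts must be nonnegative")
    if (length(categorical_level_counts) != n_clinical_categorical)
      stop("categorical_level_counts must have length n_clinical_categorical")
    if (n_clinical_categorical > 0 && any(categorical_level_counts < 2))
      stop("categorical level counts must be >= 2")
    if (nrow(signal_features) > 0) {
      p <- n_clinical_continuous + n_clinical_categorical + n_metabolites
      if (any(signal_features$index < 1 | signal_features$index > p))
        stop("signal feature index out of range (1..", p, ")")
      if (any(!is.finite(signal_features$beta)))
        stop("signal coefficients must be finite")
    }
    if (missing_col_rate < 0 || missing_col_rate > 1 ||
        missing_row_rate < 0 || missing_row_rate > 1)
      stop("missingness rates must lie in [0,1]")
  })
  invisible(spec)
}

cohort_feature_meta <- function(spec) {
  cont_names <- if (spec$n_clinical_continuous == length(.default_clinical_continuous))
    .default_clinical_continuous else sprintf("clin_c%02d", seq_len(spec$n_clinical_continuous))
  cat_names <- if (spec$n_clinical_categorical == length(.default_clinical_categorical))
    names(.default_clinical_categorical) else sprintf("clin_k%02d", seq_len(spec$n_clinical_categorical))
  met_names <- sprintf("met_%03d", seq_len(spec$n_metabolites))
  data.frame(
    name = c(cont_names, cat_names, met_names),
    kind = c(rep("clinical-continuous", spec$n_clinical_continuous),
             rep("clinical-categorical", spec$n_clinical_categorical),
             rep("metabolite", spec$n_metabolites)),
    levels = c(rep(NA_integer_, spec$n_clinical_continuous),
               spec$categorical_level_counts,
               rep(NA_integer_, spec$n_metabolites)),
    stringsAsFactors = FALSE)
}

#' Construct a cohort object
#'
#' A cohort is the package's central container: an `n x p` numeric matrix
#' (categorical variables integer-coded, `NA` marking missing cells), a
#' binary outcome vector (1 = incident case), record identifiers, and
#' per-feature metadata (`name`, `kind`, `levels`).
#'
#' @param X numeric matrix.
#' @param y binary labels.
#' @param meta data.frame with columns name/kind/levels.
#' @param ids unique record identifiers.
#' @param raw_metabolites enforce strict positivity of observed metabolite
#'   values (the raw-scale invariant); disable for cohorts already log
#'   transformed or scaled.
#' @return an object of class `cohort`.
#' @export
new_cohort <- function(X, y, meta, ids = NULL, raw_metabolites = TRUE) {
  X <- as.matrix(X)
  if (is.null(ids)) ids <- sprintf("R%05d", seq_len(nrow(X)))
  if (anyDuplicated(ids)) stop("duplicate record ids")
  if (length(y) != nrow(X)) stop("label length must match rows of X")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (nrow(meta) != ncol(X)) stop("meta must describe every feature column")
  met <- meta$kind == "metabolite"
  if (any(met) && raw_metabolites) {
    vals <- X[, met, drop = FALSE]
    if (any(vals <= 0 & !is.na(vals)))
      stop("metabolite values must be strictly positive where observed")
  }
  colnames(X) <- meta$name
  structure(list(ids = as.character(ids), X = X, y = as.integer(y), meta = meta),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(factor(x$y, levels = c(0, 1)))
  cat(sprintf("<cohort> %d records x %d features (%d negative / %d positive)\n",
              nrow(x$X), ncol(x$X), tab["0"], tab["1"]))
  kinds <- table(x$meta$kind)
  cat("  features:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  nm <- sum(is.na(x$X))
  if (nm > 0) cat(sprintf("  missing cells: %d (%.1f%%)\n", nm, 100 * nm / length(x$X)))
  invisible(x)
}

#' Subset a cohort by record
#'
#' @param cohort a `cohort`.
#' @param i record ids (character) or row indices.
#' @return the subsetted `cohort`.
#' @export
cohort_subset <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$ids)
  if (anyNA(i)) stop("unknown record ids")
  structure(list(ids = cohort$ids[i], X = cohort$X[i, , drop = FALSE],
                 y = cohort$y[i], meta = cohort$meta), class = "cohort")
}

# Linear-predictor contribution of the planted signal features: stored
# value for clinical features, z-scored log value for metabolites (whose
# raw log-normal scale is arbitrary).
signal_eta <- function(X, spec, meta) {
  sig <- spec$signal_features
  if (nrow(sig) == 0) return(numeric(nrow(X)))
  eta <- numeric(nrow(X))
  met_offset <- spec$n_clinical_continuous + spec$n_clinical_categorical
  for (r in seq_len(nrow(sig))) {
    j <- sig$index[r]
    v <- X[, j]
    if (meta$kind[j] == "metabolite") {
      jm <- j - met_offset
      v <- (log(v) - spec$metabolite_log_mean[jm]) / spec$metabolite_log_sd[jm]
    }
    eta <- eta + sig$beta[r] * v
  }
  eta
}

draw_features <- function(m, spec) {
  blocks <- list()
  if (spec$n_clinical_continuous > 0)
    blocks$cont <- matrix(stats::rnorm(m * spec$n_clinical_continuous),
                          m, spec$n_clinical_continuous)
  if (spec$n_clinical_categorical > 0)
    blocks$cat <- sapply(spec$categorical_level_counts, function(L)
      sample.int(L, m, replace = TRUE))
  if (spec$n_metabolites > 0) {
    Z <- matrix(stats::rnorm(m * spec$n_metabolites), m, spec$n_metabolites)
    blocks$met <- exp(add_row(Z * matrix(spec$metabolite_log_sd, m,
                                         spec$n_metabolites, byrow = TRUE),
                              spec$metabolite_log_mean))
  }
  do.call(cbind, blocks)
}

#' Simulate a cohort
#'
#' Draws records feature-first, then assigns the outcome from a logistic
#' model on the spec's signal features. The intercept is solved numerically
#' so the expected prevalence equals
#' `n_positive / (n_positive + n_negative)`, and records are then
#' accumulated until both class quotas are met exactly, so every simulated
#' cohort has the exact class counts of its spec.
#'
#' @param spec a [cohort_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return a [new_cohort()] object with exact class counts.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_negative = 50, n_positive = 10,
#'                                   n_metabolites = 20, seed = 7))
#' table(co$y)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  validate_cohort_spec(spec)
  if (is.null(seed)) seed <- spec$seed
  meta <- cohort_feature_meta(spec)
  n_pos <- spec$n_positive; n_neg <- spec$n_negative
  target_prev <- n_pos / (n_pos + n_neg)
  with_seed(seed, {
    pool <- draw_features(max(4000L, 2L * (n_pos + n_neg)), spec)
    eta_pool <- signal_eta(pool, spec, meta)
    alpha <- if (nrow(spec$signal_features) == 0) stats::qlogis(target_prev) else
      stats::uniroot(function(a) mean(stats::plogis(a + eta_pool)) - target_prev,
                     interval = c(-40, 40))$root
    Xp <- NULL; Xn <- NULL
    take <- function(acc, M, need) rbind(acc, M[seq_len(min(nrow(M), need)), , drop = FALSE])
    chunk <- pool
    eta <- eta_pool
    repeat {
      yc <- stats::rbinom(nrow(chunk), 1, stats::plogis(alpha + eta))
      if (nrow_or0(Xp) < n_pos)
        Xp <- take(Xp, chunk[yc == 1, , drop = FALSE], n_pos - nrow_or0(Xp))
      if (nrow_or0(Xn) < n_neg)
        Xn <- take(Xn, chunk[yc == 0, , drop = FALSE], n_neg - nrow_or0(Xn))
      if (nrow_or0(Xp) >= n_pos && nrow_or0(Xn) >= n_neg) break
      chunk <- draw_features(4000L, spec)
      eta <- signal_eta(chunk, spec, meta)
    }
    X <- rbind(Xp, Xn)
    y <- c(rep(1L, n_pos), rep(0L, n_neg))
    ord <- sample.int(nrow(X))
    new_cohort(X[ord, , drop = FALSE], y[ord], meta,
               ids = sprintf("S%05d", seq_len(nrow(X))))
  })
}

nrow_or0 <- function(M) if (is.null(M)) 0L else nrow(M)

#' Inject completely-at-random missingness into metabolite columns/rows
#'
#' Designated metabolite columns receive missing markers at
#' `missing_col_rate`, and designated records receive missing markers across
#' their metabolite columns at `missing_row_rate`. Clinical columns are
#' never touched. Missingness is MCAR.
#'
#' @param cohort a `cohort`.
#' @param spec a [cohort_spec()] carrying the rates and designation counts.
#' @param cols,rows optional explicit designation: metabolite column indices
#'   (within the metabolite block) and row indices. When `NULL`, designated
#'   at random per the spec counts.
#' @param seed RNG seed (default `spec$seed + 1`).
#' @return the cohort with `NA` markers added.
#' @export
inject_missingness <- function(cohort, spec, cols = NULL, rows = NULL, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed + 1L
  met_cols <- which(cohort$meta$kind == "metabolite")
  with_seed(seed, {
    if (is.null(cols)) cols <- if (spec$n_missing_cols > 0)
      sample(seq_along(met_cols), min(spec$n_missing_cols, length(met_cols))) else integer()
    if (is.null(rows)) rows <- if (spec$n_missing_rows > 0)
      sample(nrow(cohort$X), min(spec$n_missing_rows, nrow(cohort$X))) else integer()
    X <- cohort$X
    if (spec$missing_col_rate > 0) for (j in met_cols[cols]) {
      hit <- stats::runif(nrow(X)) < spec$missing_col_rate
      X[hit, j] <- NA_real_
    }
    if (spec$missing_row_rate > 0) for (i in rows) {
      hit <- stats::runif(length(met_cols)) < spec$missing_row_rate
      X[i, met_cols[hit]] <- NA_real_
    }
    cohort$X <- X
    cohort
  })
}

#' Simulate a cohort with no feature-outcome association
#'
#' Every feature is drawn independently of the label: the null configuration
#' used to demonstrate majority-class collapse of conventional classifiers
#' under severe imbalance.
#'
#' @param n_negative,n_positive exact class counts.
#' @param p number of (continuous) features.
#' @param seed RNG seed.
#' @return a `cohort` with `p` clinical-continuous features.
#' @export
no_signal_cohort <- function(n_negative = 1376, n_positive = 78, p = 382, seed = 1L) {
  stopifnot(n_negative >= 1, n_positive >= 1, p >= 1)
  n <- n_negative + n_positive
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    y <- sample(c(rep(1L, n_positive), rep(0L, n_negative)))
    meta <- data.frame(name = sprintf("f%03d", seq_len(p)),
                       kind = "clinical-continuous", levels = NA_integer_,
                       stringsAsFactors = FALSE)
    new_cohort(X, y, meta, ids = sprintf("N%05d", seq_len(n)))
  })
}

#' Write / read a cohort as CSV plus metadata sidecar
#'
#' The CSV has columns `id,label,<feature...>` with missing cells encoded as
#' empty strings; the sidecar `<path>.meta.json` holds the per-feature
#' metadata. The same `(spec, seed)` always yields a byte-identical file.
#'
#' @param cohort a `cohort`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(id = cohort$ids, label = cohort$y,
                   as.data.frame(cohort$X), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(cohort$meta, paste0(path, ".meta.json"),
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @param raw_metabolites passed to [new_cohort()]; the file may hold a
#'   cohort at any processing stage, so positivity is not enforced by
#'   default.
#' @export
read_cohort <- function(path, raw_metabolites = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "")
  meta <- as.data.frame(jsonlite::read_json(paste0(path, ".meta.json"),
                                            simplifyVector = TRUE))
  meta$levels <- suppressWarnings(as.integer(meta$levels))
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(X) <- "double"
  new_cohort(X, df$label, meta, ids = df$id, raw_metabolites = raw_metabolites)
}
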