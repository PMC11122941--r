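# End-to-end three-step pipeline: simulate (or load) a cohort, clean and
# scale it, group + split, train the adversarial pair on the positive
# records of the train + test partitions, generate feature-enhanced
# positives, balance the training pool, train the MLP with the chosen
# loss, evaluate on the held-out partitions, and run the mean-replacement
# sensitivity analysis -- replicated with deterministic per-stage seeds
# derived from one master seed. The validation partition is never seen by
# the GAN, the resampler, or MLP training; it is used only for final
# evaluation.

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with defaults matching the
#' study conditions: 64/16/20 grouped split over 3 feature-space groups,
#' GAN at 3000 steps (lr 0.005, weight decay 1e-4), 2600 generated records,
#' balancing in batches of 100 toward a majority target of 1000 with two
#' passes, MLP at 200 epochs (lr 5e-5), GFE loss, 10 replicates.
#'
#' @param cohort a [cohort_spec()] (simulated per replicate) or a path to a
#'   cohort CSV written by [write_cohort()] (loaded once, resplit per
#'   replicate).
#' @param metabolite_threshold,participant_threshold missingness filters.
#' @param impute_sweeps chained-imputation sweeps.
#' @param k_groups,fractions grouping and split settings.
#' @param gan,mlp,balance stage hyperparameter lists; see [gan_fit()],
#'   [mlp_fit()], [iterative_balance()].
#' @param n_generated generated records per replicate.
#' @param loss `"gfe"` or `"bce"`.
#' @param replicates number of full resplit-retrain-evaluate replicates.
#' @param sensitivity_top_k features flagged in the aggregated ranking.
#' @param seed master seed; every stage seed is derived from it and the
#'   replicate index.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            metabolite_threshold = 0.20,
                            participant_threshold = 0.10,
                            impute_sweeps = 10,
                            k_groups = 3,
                            fractions = c(0.64, 0.16, 0.20),
                            gan = list(), mlp = list(), balance = list(),
                            n_generated = 2600,
                            loss = c("gfe", "bce"),
                            replicates = 10,
                            sensitivity_top_k = 20,
                            seed = 1L) {
  loss <- match.arg(loss)
  gan <- utils::modifyList(list(steps = 3000, lr = 0.005, weight_decay = 1e-4,
                                sigma_z = 0.1,
                                disc_widths = c(200, 200, 200, 100),
                                gen_encoder_widths = c(300, 75),
                                gen_decoder_widths = c(150)), gan)
  mlp <- utils::modifyList(list(lr = 5e-5, weight_decay = 1e-4, epochs = 200,
                                batch_size = 64, hidden = NULL), mlp)
  balance <- utils::modifyList(list(batch = 100, target_majority = 1000,
                                    repeats = 2, k_smote = 5, k_enn = 3),
                               balance)
  structure(list(cohort = cohort,
                 metabolite_threshold = metabolite_threshold,
                 participant_threshold = participant_threshold,
                 impute_sweeps = impute_sweeps, k_groups = k_groups,
                 fractions = fractions, gan = gan, mlp = mlp,
                 balance = balance, n_generated = n_generated, loss = loss,
                 replicates = replicates,
                 sensitivity_top_k = sensitivity_top_k,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic stage seed: master seed, replicate index, stage index
stage_seed <- function(master, replicate, stage) {
  as.integer((as.numeric(master) + 104729 * replicate + 7919 * stage) %% .Machine$integer.max)
}

#' Run the full pipeline
#'
#' Executes every stage per replicate (a stage error aborts that replicate
#' with a logged cause; remaining replicates proceed) and aggregates the
#' evaluation metrics and sensitivity rankings across completed
#' replicates.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return an object of class `pipeline_report`: per-replicate results,
#'   aggregated means, the aggregated [aggregate_and_rank()] sensitivity
#'   report, and the resolved config.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  base_cohort <- if (is.character(config$cohort)) read_cohort(config$cohort) else NULL
  reps <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    reps[[r]] <- tryCatch(
      run_replicate(config, r, base_cohort, verbose = verbose),
      error = function(e) {
        warning(sprintf("replicate %d aborted: %s", r, conditionMessage(e)))
        structure(list(error = conditionMessage(e)), class = "pipeline_replicate")
      })
  }
  ok <- !vapply(reps, function(x) !is.null(x$error), logical(1))
  summary <- if (any(ok)) {
    grab <- function(f) mean(vapply(reps[ok], f, numeric(1)), na.rm = TRUE)
    list(
      n_replicates = sum(ok),
      test_balanced_accuracy = grab(function(x) x$eval_test$balanced_accuracy),
      test_accuracy = grab(function(x) x$eval_test$accuracy),
      validation_balanced_accuracy = grab(function(x) x$eval_validation$balanced_accuracy),
      validation_accuracy = grab(function(x) x$eval_validation$accuracy),
      validation_sensitivity = grab(function(x) x$eval_validation$sensitivity))
  } else list(n_replicates = 0L)
  sens <- if (any(ok))
    aggregate_and_rank(lapply(reps[ok], `[[`, "sensitivity"),
                       top_k = config$sensitivity_top_k) else NULL
  structure(list(replicates = reps, summary = summary, sensitivity = sens,
                 config = config),
            class = "pipeline_report")
}

run_replicate <- function(config, r, base_cohort = NULL, verbose = FALSE) {
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  say <- function(...) if (verbose) message(sprintf("[replicate %d] ", r), ...)
  t0 <- tic()

  cohort <- if (!is.null(base_cohort)) base_cohort else
    simulate_cohort(config$cohort, seed = stage_seed(config$seed, r, 1))
  if (inherits(config$cohort, "cohort_spec") &&
      (config$cohort$missing_col_rate > 0 || config$cohort$missing_row_rate > 0))
    cohort <- inject_missingness(cohort, config$cohort,
                                 seed = stage_seed(config$seed, r, 2))
  timings["simulate"] <- tic() - t0; t0 <- tic()

  cohort <- filter_metabolites_by_missingness(cohort, config$metabolite_threshold)
  cohort <- filter_participants_by_missingness(cohort, config$participant_threshold)
  cohort <- log_transform_metabolites(cohort)
  cohort <- impute_chained(cohort, n_sweeps = config$impute_sweeps)
  timings["preprocess"] <- tic() - t0; t0 <- tic()

  # grouping geometry uses a provisional whole-cohort scaling; the final
  # scaler is refitted on the training partition only
  groups <- cluster_groups(minmax_apply(minmax_fit(cohort), cohort),
                           k = config$k_groups,
                           seed = stage_seed(config$seed, r, 3))
  split <- stratified_split(cohort, groups, config$fractions,
                            seed = stage_seed(config$seed, r, 4))
  scaler <- minmax_fit(cohort_subset(cohort, split$train))
  sc <- minmax_apply(scaler, cohort)
  part <- function(ids) cohort_subset(sc, ids)
  train <- part(split$train); test <- part(split$test)
  validation <- part(split$validation)
  timings["split"] <- tic() - t0; t0 <- tic()

  # adversarial training on positives of train + test only
  gan_pos <- rbind(train$X[train$y == 1, , drop = FALSE],
                   test$X[test$y == 1, , drop = FALSE])
  say(sprintf("GAN on %d positives", nrow(gan_pos)))
  gan <- do.call(gan_fit, c(list(positives = gan_pos,
                                 seed = stage_seed(config$seed, r, 5)),
                            config$gan))
  generated <- generate_records(gan, gan_pos, n = config$n_generated,
                                seed = stage_seed(config$seed, r, 6))
  timings["gan"] <- tic() - t0; t0 <- tic()

  balanced <- do.call(iterative_balance,
                      c(list(observed = train$X, labels = train$y,
                             generated = generated,
                             seed = stage_seed(config$seed, r, 7)),
                        config$balance))
  timings["balance"] <- tic() - t0; t0 <- tic()

  refs <- reference_sets(P = gan_pos,
                         N = train$X[train$y == 0, , drop = FALSE])
  say("training MLP")
  model <- do.call(mlp_fit, c(
    list(X = balanced$X, y = balanced$y,
         observed_mask = as.integer(balanced$provenance == "observed"),
         loss = config$loss, gan = gan, refs = refs,
         eval_sets = list(test = list(X = test$X, y = test$y),
                          validation = list(X = validation$X, y = validation$y)),
         seed = stage_seed(config$seed, r, 8)),
    config$mlp))
  timings["mlp"] <- tic() - t0; t0 <- tic()

  eval_test <- evaluate(model, test$X, test$y)
  eval_validation <- evaluate(model, validation$X, validation$y)

  means <- nonmi_feature_means(sc)
  sens <- mean_replacement_sensitivity(
    model, sc$X[sc$y == 1, , drop = FALSE], means)
  timings["evaluate"] <- tic() - t0

  structure(list(split = split, n_gan_positives = nrow(gan_pos),
                 n_balance_observed = sum(balanced$provenance == "observed"),
                 gan_history = gan$history,
                 balance_log = balanced$log, model_curves = model$curves,
                 eval_test = eval_test, eval_validation = eval_validation,
                 sensitivity = sens, timings = timings,
                 seeds = vapply(1:8, function(s) stage_seed(config$seed, r, s),
                                numeric(1)),
                 error = NULL),
            class = "pipeline_replicate")
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_report> %d/%d replicates completed, loss = %s\n",
              s$n_replicates, x$config$replicates, x$config$loss))
  if (s$n_replicates > 0) {
    cat(sprintf("  test:       accuracy %.3f, balanced %.3f\n",
                s$test_accuracy, s$test_balanced_accuracy))
    cat(sprintf("  validation: accuracy %.3f, balanced %.3f, sensitivity %.3f\n",
                s$validation_accuracy, s$validation_balanced_accuracy,
                s$validation_sensitivity))
  }
  invisible(x)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalars and stage sublists mirror the arguments of [pipeline_config()];
#' a `cohort` sublist is passed to [cohort_spec()], a `cohort_file` string
#' is used as a cohort path.
#'
#' @param path YAML (needs the yaml package) or JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- obj
  if (!is.null(obj$cohort_file)) {
    args$cohort <- obj$cohort_file
    args$cohort_file <- NULL
  } else if (!is.null(obj$cohort)) {
    args$cohort <- do.call(cohort_spec, as.list(obj$cohort))
  }
  do.call(pipeline_config, args)
}
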