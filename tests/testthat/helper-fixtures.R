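# Shared fixtures, built lazily and cached for the whole run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Easy two-feature positive cloud inside [0,1], the toy the adversarial
# pair should learn to reproduce.
toy_positive_cloud <- function() fixture("cloud", function() {
  set.seed(9)
  cbind(runif(80, 0.6, 0.8), runif(80, 0.2, 0.4))
})

toy_gan_args <- list(sigma_z = 0.05, disc_widths = c(16, 8),
                     gen_encoder_widths = c(8, 4), gen_decoder_widths = c(8))

toy_gan <- function() fixture("gan", function() {
  do.call(gan_fit, c(list(positives = toy_positive_cloud(), steps = 1000,
                          seed = 5), toy_gan_args))
})

toy_gan_untrained <- function() fixture("gan0", function() {
  do.call(gan_fit, c(list(positives = toy_positive_cloud(), steps = 2,
                          seed = 5), toy_gan_args))
})

# Linearly separable two-class toy for predictor sanity checks.
separable_set <- function() fixture("sep", function() {
  set.seed(4)
  X <- rbind(matrix(runif(100, 0, 0.4), 50, 2),
             matrix(runif(100, 0.6, 1), 50, 2))
  list(X = X, y = c(rep(0L, 50), rep(1L, 50)))
})

# Default-schema cohort (study-scale counts) shared by wiring checks.
default_cohort <- function() fixture("default_cohort", function() {
  simulate_cohort(cohort_spec(seed = 5))
})

# A model whose predictions are a fixed function of nothing: used to probe
# evaluate() with hand-built score vectors.
stub_model <- function(scores) structure(list(scores = scores), class = "stub_model")
predict.stub_model <- function(object, newdata, type = "response", ...) {
  rep_len(object$scores, nrow(as.matrix(newdata)))
}
registerS3method("predict", "stub_model", predict.stub_model,
                 envir = asNamespace("stats"))
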