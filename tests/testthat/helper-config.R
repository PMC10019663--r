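# Random valid parameter sets for property-style tests. Draws stage-1
# simplex weights, incident rates inside (0, r_max), call probabilities with
# a positive self-manage residual, and an observed repeat rate kept safely
# inside the calibration-feasible region of each arm.
random_config <- function() {
  cfg <- default_config()
  for (arm in c("hs2", "sc")) {
    tr <- cfg$transitions[[arm]]
    k <- length(tr$stage1)
    w <- stats::runif(k, 0.05, 1)
    tr$stage1[] <- w / sum(w)
    tr$rates[] <- stats::runif(k, 0.05, 1.6)
    p31 <- stats::runif(k, 0.05, 0.6)
    p32 <- stats::runif(k, 0.05, 0.95 - p31)
    tr$p31[] <- p31
    tr$p32[] <- p32
    cfg$transitions[[arm]] <- tr
    sigma <- severity_pathway_sum(arm, cfg)
    cfg$transitions[[arm]]$observed_repeat_rate <-
      stats::runif(1, 0, 0.9) * sigma
  }
  validate_config(cfg)
  cfg
}

# Configuration in which the HS2 arm is structurally identical to standard
# care except for the intervention cost: same type mix, rates, call
# probabilities, observed rate and self-manage mix.
identical_arms_config <- function() {
  cfg <- default_config()
  cfg$transitions$hs2$stage1 <- c(read_action = 0.25, read_only = 0,
                                  no_action = 0.75)
  cfg$transitions$hs2$rates <- c(read_action = 0.75, read_only = 0.9,
                                 no_action = 1.0)
  cfg$transitions$hs2$p31 <- c(read_action = 0.4, read_only = 0.4,
                               no_action = 0.4)
  cfg$transitions$hs2$p32 <- c(read_action = 0.35, read_only = 0.35,
                               no_action = 0.35)
  cfg$transitions$hs2$observed_repeat_rate <- 0.055
  cfg$self_manage$read_action <- cfg$self_manage$other
  validate_config(cfg)
  cfg
}
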