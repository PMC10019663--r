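# Vectorised closed-form evaluation of one arm over many parameter draws.
#
# Every summary the model produces (outcome distribution, provider costs,
# per-type continuation costs) is arithmetic in the parameters, so draws can
# be evaluated as vector algebra instead of rebuilding the pathway table per
# draw. Agreement with the pathway enumeration of build_arm() is asserted in
# the test suite; probabilistic analyses use this evaluator for speed.
#
# `rates` is a draws x types matrix of per-fortnight incident rates (columns
# in the order of the arm's stage-1 types) and `observed_rate` a vector of
# repeat-attendance rates; both default to the configuration baseline.

arm_evaluate <- function(arm, config = default_config(), rates = NULL,
                         observed_rate = NULL) {
  spec <- arm_spec(arm, config)
  types <- spec$types
  k <- length(types)
  if (is.null(rates)) {
    rates <- matrix(vapply(types, function(ty) ty$rate, numeric(1)),
                    nrow = 1)
  }
  rates <- as.matrix(rates)
  stopifnot(ncol(rates) == k)
  if (is.null(observed_rate)) observed_rate <- spec$observed_rate
  n <- max(nrow(rates), length(observed_rate))
  if (nrow(rates) == 1L && n > 1L) {
    rates <- rates[rep(1L, n), , drop = FALSE]
  }
  observed_rate <- rep_len(observed_rate, n)

  p <- spec$pieces
  p5 <- spec$convey
  p6 <- spec$admit
  # expected stage-3 provider cost per EMS attendance
  attend <- p5 * (p$stc + p6 * p$ed_ha + (1 - p6) * p$ed) + (1 - p5) * p$str

  p2 <- 1 - exp(-rates)                      # draws x types
  s1 <- vapply(types, function(ty) ty$stage1_prob, numeric(1))
  p31 <- vapply(types, function(ty) ty$p31, numeric(1))
  p32 <- vapply(types, function(ty) ty$p32, numeric(1))
  sigma_pi <- drop(p2 %*% (s1 * (p31 + p32)))
  p4 <- ifelse(sigma_pi > 0, observed_rate / sigma_pi,
               ifelse(observed_rate == 0, 0, NA_real_))
  feasible <- !is.na(p4) & p4 <= 1

  p0 <- drop(exp(-rates) %*% s1)
  p_s <- observed_rate
  p_ns <- 1 - p0 - p_s

  # provider-attributed expected costs; stage-1 costs are draw-independent
  cost <- matrix(0, n, 4, dimnames = list(NULL, PROVIDERS))
  stage1 <- Reduce(`+`, lapply(types, function(ty) {
    ty$stage1_prob * ty$stage1_cost
  }))
  cost <- cost + matrix(stage1, n, 4, byrow = TRUE)

  # per-type conditional recurrence-management cost (total GBP, per draw)
  cont <- matrix(0, n, k, dimnames = list(NULL, names(types)))
  for (j in seq_len(k)) {
    ty <- types[[j]]
    resid <- 1 - ty$p31 - ty$p32
    # provider components, draws x 4
    per_rec <-
      outer(rep(1, n), ty$p31 * p$call999 + ty$p32 * p$call111 +
                       resid * ty$sm_cost) +
      outer(p4 * (ty$p31 + ty$p32), attend) +
      outer(p4 * ty$p32, p$redirect) +
      outer((1 - p4) * ty$p31, p$htr) +
      outer((1 - p4) * ty$p32, p$pw111)
    cost <- cost + (ty$stage1_prob * p2[, j]) * per_rec
    cont[, j] <- p2[, j] * rowSums(per_rec)
  }

  type_stage1 <- vapply(types, function(ty) sum(ty$stage1_cost), numeric(1))
  list(
    arm = spec$arm,
    n = n,
    feasible = feasible,
    p4 = p4,
    sigma_pi = sigma_pi,
    p0 = p0, p_ns = p_ns, p_s = p_s,
    cost = cost,
    total = rowSums(cost),
    # continuation cost per cycle for each patient type (recurrence
    # management only, one-off stage-1 costs excluded)
    type_continuation = cont,
    # conditional total cost per patient type including stage-1 costs
    type_total = sweep(cont, 2, type_stage1, `+`),
    type_stage1_prob = s1
  )
}
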