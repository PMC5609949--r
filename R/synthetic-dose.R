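#' Dose-response simulation configuration
#'
#' Parameters of the median-effect generator. The model is the
#' median-effect equation `fa/(1 - fa) = (D/Dm)^m`: `Dm` is the dose
#' giving 50% effect (the IC50 under this model) and `m` is the
#' sigmoidicity slope. Noise is additive on the logit (log-odds) scale,
#' the scale on which the model is linear, so simulated fractions
#' affected stay strictly inside (0, 1).
#'
#' @param m median-effect slope (> 0, unitless).
#' @param Dm median-effect dose in uM (> 0).
#' @param doses vector of doses in uM (all > 0).
#' @param replicates replicates per dose (>= 1).
#' @param noise_sd standard deviation of logit-scale noise (>= 0).
#' @param seed integer seed.
#' @return a validated `dose_response_sim_config` list.
#' @export
dose_response_sim_config <- function(m = 1.5, Dm = 1,
                                     doses = 2^(-3:4), replicates = 3L,
                                     noise_sd = 0.05, seed = 1L) {
  if (m <= 0) stop("`m` must be positive")
  if (Dm <= 0) stop("`Dm` must be positive")
  if (length(doses) == 0L || any(doses <= 0)) {
    stop("all `doses` must be positive")
  }
  if (replicates < 1L) stop("`replicates` must be at least 1")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(
    list(
      m = m, Dm = Dm, doses = as.numeric(doses),
      replicates = as.integer(replicates),
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "dose_response_sim_config"
  )
}

#' Simulate a single-drug dose-response table
#'
#' For each dose D and replicate, the fraction affected is drawn as
#' `logit(fa) = m * (ln D - ln Dm) + e`, `e ~ Normal(0, noise_sd)`.
#' With `noise_sd = 0` the output lies exactly on the median-effect
#' curve, so [fit_median_effect()] recovers `(m, Dm)` to machine
#' precision.
#'
#' @param config a [dose_response_sim_config()].
#' @return data.frame with columns `dose`, `replicate`, `fa`
#'   (fa strictly in (0, 1)).
#' @export
simulate_dose_response <- function(config = dose_response_sim_config()) {
  if (!inherits(config, "dose_response_sim_config")) {
    stop("`config` must be a dose_response_sim_config")
  }
  with_seed(fan_seed(config$seed, "dose"), {
    grid <- expand.grid(
      replicate = seq_len(config$replicates),
      dose = config$doses
    )[, c("dose", "replicate")]
    eta <- config$m * (log(grid$dose) - log(config$Dm)) +
      rnorm(nrow(grid), 0, config$noise_sd)
    data.frame(
      dose = grid$dose,
      replicate = grid$replicate,
      fa = plogis(eta)
    )
  })
}

#' Simulate combination dose-response with known interaction
#'
#' Ground truth for combination-index recovery. At each dose pair
#' `(d1, d2)` the noiseless fraction affected solves the Loewe
#' additivity relation scaled by the interaction multiplier:
#' `d1/Dx1(fa) + d2/Dx2(fa) = 1/interaction`, where `Dx_i(fa)` is the
#' single-drug dose of drug i producing effect `fa` under its
#' median-effect parameters. Recomputing the combination index on this
#' output therefore returns `1/interaction` exactly: `interaction = 1`
#' is Loewe-additive (CI = 1), `interaction > 1` synergistic (CI < 1),
#' `interaction < 1` antagonistic (CI > 1). Logit-scale noise is added
#' as in [simulate_dose_response()].
#'
#' @param fit1,fit2 single-drug parameters: lists or
#'   [median_effect_fit] objects with elements `m` and `Dm`.
#' @param dose_pairs data.frame with columns `d1`, `d2` (uM; one may be
#'   zero, not both).
#' @param interaction potency multiplier on the Loewe-additive combined
#'   dose (> 0).
#' @param replicates replicates per pair.
#' @param noise_sd logit-scale noise standard deviation.
#' @param seed integer seed.
#' @return data.frame with columns `d1`, `d2`, `replicate`, `fa`.
#' @export
simulate_combination <- function(fit1, fit2, dose_pairs,
                                 interaction = 1, replicates = 1L,
                                 noise_sd = 0, seed = 1L) {
  if (interaction <= 0) stop("`interaction` must be positive")
  if (!all(c("d1", "d2") %in% names(dose_pairs))) {
    stop("`dose_pairs` needs columns `d1` and `d2`")
  }
  if (any(dose_pairs$d1 < 0 | dose_pairs$d2 < 0) ||
      any(dose_pairs$d1 + dose_pairs$d2 <= 0)) {
    stop("dose pairs must be non-negative with d1 + d2 > 0")
  }
  fa0 <- vapply(
    seq_len(nrow(dose_pairs)),
    function(i) {
      loewe_effect(
        dose_pairs$d1[i], dose_pairs$d2[i],
        fit1$m, fit1$Dm, fit2$m, fit2$Dm, interaction
      )
    },
    numeric(1)
  )
  with_seed(fan_seed(seed, "combination"), {
    idx <- rep(seq_len(nrow(dose_pairs)), each = replicates)
    eta <- qlogis(fa0[idx]) + rnorm(length(idx), 0, noise_sd)
    data.frame(
      d1 = dose_pairs$d1[idx],
      d2 = dose_pairs$d2[idx],
      replicate = rep(seq_len(replicates), times = nrow(dose_pairs)),
      fa = plogis(eta)
    )
  })
}

# solve d1/Dx1(fa) + d2/Dx2(fa) = 1/alpha for fa; closed form when the
# two slopes are equal, otherwise bisection-free uniroot on logit(fa)
loewe_effect <- function(d1, d2, m1, Dm1, m2, Dm2, alpha) {
  if (d2 == 0) {
    return(plogis(m1 * log(alpha * d1 / Dm1)))
  }
  if (d1 == 0) {
    return(plogis(m2 * log(alpha * d2 / Dm2)))
  }
  if (isTRUE(all.equal(m1, m2))) {
    # R^(1/m) = alpha * (d1/Dm1 + d2/Dm2), R = fa/(1 - fa)
    return(plogis(m1 * log(alpha * (d1 / Dm1 + d2 / Dm2))))
  }
  f <- function(eta) {
    r <- exp(eta) # fa/(1 - fa)
    d1 / (Dm1 * r^(1 / m1)) + d2 / (Dm2 * r^(1 / m2)) - 1 / alpha
  }
  eta <- uniroot(f, lower = -60, upper = 60, tol = 1e-14)$root
  plogis(eta)
}
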