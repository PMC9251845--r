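#' Patch layout of the environment
#'
#' The environment consists of `n1` patches holding only host species 1
#' and `n2` patches holding only host species 2; patch identity is fixed
#' for the whole simulation.
#'
#' @param p A `"trap_params"` object.
#' @return Integer vector of patch species, length `n1 + n2` (patch ids
#'   are positions in this vector).
#' @export
patch_layout <- function(p) {
  stopifnot(inherits(p, "trap_params"))
  rep(c(1L, 2L), times = c(p$n1, p$n2))
}

#' Stochastic Ricker offspring production, per patch
#'
#' The surviving adults of a host species reproduce and scatter their
#' offspring uniformly over that species' patches. The offspring count of
#' each patch is an independent Poisson draw with mean
#' `lambda = (1/n) * r * H * exp(-H / K)`, where `H` is the adult count
#' (survivors of the previous generation). Density regulation and
#' reproduction are this one combined step; there is no separate survival
#' draw.
#'
#' @param H_prev Adult count before reproduction (non-negative integer).
#' @param p A `"trap_params"` object.
#' @param species Host species (1 or 2) whose parameters to use.
#' @return Integer vector of offspring counts, one per patch of the
#'   species.
#' @export
spawn_offspring <- function(H_prev, p, species) {
  stopifnot(inherits(p, "trap_params"), H_prev >= 0,
            species %in% c(1L, 2L))
  n <- if (species == 1L) p$n1 else p$n2
  lambda <- ricker_patch_mean(H_prev, p, species)
  stats::rpois(n, lambda)
}

#' Per-patch Ricker mean
#'
#' The deterministic part of [spawn_offspring()]:
#' `(1/n) * r * H * exp(-H / K)`.
#'
#' @inheritParams spawn_offspring
#' @return A single number, the Poisson mean per patch.
#' @export
ricker_patch_mean <- function(H_prev, p, species) {
  stopifnot(inherits(p, "trap_params"), species %in% c(1L, 2L))
  n <- if (species == 1L) p$n1 else p$n2
  r <- if (species == 1L) p$r1 else p$r2
  K <- if (species == 1L) p$K1 else p$K2
  (1 / n) * r * H_prev * exp(-H_prev / K)
}

#' Create a host cohort with exponential sensitive periods
#'
#' Turns per-patch offspring counts into individual hosts. Each host's
#' maturation time (the end of its sensitive, parasitizable period,
#' measured from the start of the generation) is an independent
#' exponential draw with mean `tau_dH`. All hosts start alive and
#' vulnerable with unresolved fate.
#'
#' @param counts Integer vector of offspring per patch (as returned by
#'   [spawn_offspring()]).
#' @param tau_dH Mean sensitive-period length (> 0).
#' @param species Host species id recorded on each individual.
#' @param patch_ids Patch id for each element of `counts` (defaults to
#'   `seq_along(counts)`).
#' @return A data.frame (one row per host) with columns `species`,
#'   `patch`, `maturation_time`.
#' @export
sample_maturation_times <- function(counts, tau_dH, species = 1L,
                                    patch_ids = seq_along(counts)) {
  stopifnot(tau_dH > 0, all(counts >= 0), length(patch_ids) == length(counts))
  total <- sum(counts)
  data.frame(
    species = rep(as.integer(species), total),
    patch = rep(as.integer(patch_ids), times = counts),
    maturation_time = stats::rexp(total, rate = 1 / tau_dH)
  )
}

#' Initialize host cohorts at the parasitoid-free equilibrium
#'
#' The first generation's adult counts are set to `round(K * log(r))` per
#' species (the deterministic equilibrium of the Ricker map), which then
#' spawn the first offspring cohort via [spawn_offspring()] and
#' [sample_maturation_times()].
#'
#' @param p A `"trap_params"` object.
#' @return A list with `hosts` (data.frame of the combined offspring
#'   cohort of both species) and `adults` (the equilibrium adult counts,
#'   integer vector of length 2).
#' @export
initialize_hosts <- function(p) {
  stopifnot(inherits(p, "trap_params"))
  adults <- c(round(equilibrium_density(p$K1, p$r1)),
              round(equilibrium_density(p$K2, p$r2)))
  c1 <- spawn_offspring(adults[1], p, 1L)
  c2 <- spawn_offspring(adults[2], p, 2L)
  h1 <- sample_maturation_times(c1, p$tau_dH1, species = 1L,
                                patch_ids = seq_len(p$n1))
  h2 <- sample_maturation_times(c2, p$tau_dH2, species = 2L,
                                patch_ids = p$n1 + seq_len(p$n2))
  list(hosts = rbind(h1, h2), adults = as.integer(adults))
}
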