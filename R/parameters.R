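#' Model parameters for the 2-host/1-parasitoid trap simulation
#'
#' Constructs and validates the full parameter set of the model. Defaults
#' are the standard configuration of the simulation study: two host
#' species with identical demography, a parasitoid population founded by
#' specialists on host 1, and a generalist strategy that pays a
#' developmental-rate cost.
#'
#' All time parameters (`tau_*`) are in abstract model time units; the
#' model has no calendar. A "generation" is one discrete, non-overlapping
#' host/parasitoid cohort; within a generation, foraging and development
#' run in continuous time.
#'
#' @param n1,n2 Number of patches for host species 1 and 2.
#' @param r1,r2 Maximum per-capita host offspring production rates
#'   (must exceed 1 for a positive equilibrium).
#' @param K1,K2 Ricker carrying-capacity coefficients. The parasitoid-free
#'   equilibrium density is `K * log(r)`.
#' @param tau_dH1,tau_dH2 Mean length of the hosts' sensitive
#'   (parasitizable) developmental period; exponentially distributed per
#'   individual.
#' @param tau_s Mean time for a searching parasitoid to locate a host
#'   patch (patches are found at rate `1/tau_s`).
#' @param tau_a Time since the last host encounter after which a
#'   parasitoid abandons the current patch.
#' @param tau_e Mean time between encounters with one particular host
#'   individual in an occupied patch (per-host encounter rate `1/tau_e`).
#' @param tau_r Mean recovery time per unit of reproductive investment
#'   (egg laid) before search can resume.
#' @param tau_dP1,tau_dP2,tau_dP3 Mean development times of parasitoid
#'   offspring whose mother carries strategy S = 1, 2 or 3. Generalist
#'   offspring develop more slowly: `tau_dP3 > tau_dP1`.
#' @param mu_q Mutation probability of the host-preference trait per
#'   reproductive event.
#' @param mu_S Mutation probability of the parasitization strategy per
#'   reproductive event.
#' @param P0 Initial parasitoid population size.
#' @param generations Number of discrete generations to simulate.
#' @param scenario Either `1` (an incompatible attack leaves the host
#'   unharmed) or `2` (an incompatible attack kills the host without
#'   producing parasitoid offspring, i.e. non-reproductive host
#'   mortality).
#' @param seed Master RNG seed (integer); per-replicate streams are
#'   derived from it, see [trap_grid()].
#' @param matured_encounterable If `TRUE` (default), hosts that complete
#'   their sensitive period stay present in the patch and encounterable
#'   (they cost foraging time and count toward the second-encounter
#'   leaving rule) but can no longer be parasitized; if `FALSE`, matured
#'   hosts leave the encounterable pool immediately. The two readings
#'   differ only in within-generation time budgeting; see the package
#'   vignette.
#'
#' @return A validated object of class `"trap_params"` (a named list).
#' @seealso [validate_parameters()], [equilibrium_density()],
#'   [generalist_efficiency()], [trap_sim()]
#' @examples
#' p <- trap_params()
#' p$tau_dP3
#' generalist_efficiency(p)
#' @export
trap_params <- function(n1 = 20, n2 = 20,
                        r1 = 4, r2 = 4,
                        K1 = 1000, K2 = 1000,
                        tau_dH1 = 10, tau_dH2 = 10,
                        tau_s = 7,
                        tau_a = 1,
                        tau_e = 0.02,
                        tau_r = 0.5,
                        tau_dP1 = 20, tau_dP2 = 20, tau_dP3 = 46.51,
                        mu_q = 0.001,
                        mu_S = 0.01,
                        P0 = 500,
                        generations = 1000,
                        scenario = 1,
                        seed = 1L,
                        matured_encounterable = TRUE) {
  p <- list(n1 = as.integer(n1), n2 = as.integer(n2),
            r1 = as.numeric(r1), r2 = as.numeric(r2),
            K1 = as.numeric(K1), K2 = as.numeric(K2),
            tau_dH1 = as.numeric(tau_dH1), tau_dH2 = as.numeric(tau_dH2),
            tau_s = as.numeric(tau_s), tau_a = as.numeric(tau_a),
            tau_e = as.numeric(tau_e), tau_r = as.numeric(tau_r),
            tau_dP1 = as.numeric(tau_dP1), tau_dP2 = as.numeric(tau_dP2),
            tau_dP3 = as.numeric(tau_dP3),
            mu_q = as.numeric(mu_q), mu_S = as.numeric(mu_S),
            P0 = as.integer(P0),
            generations = as.integer(generations),
            scenario = as.integer(scenario),
            seed = as.integer(seed),
            matured_encounterable = isTRUE(matured_encounterable))
  class(p) <- "trap_params"
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks every model invariant and returns the parameter set unchanged if
#' all hold. The first violated invariant is reported by name.
#'
#' @param p A `"trap_params"` object (see [trap_params()]).
#' @return `p`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "trap_params"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameters: ", msg,
                                                 call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("n1", "n2", "r1", "r2", "K1", "K2", "tau_dH1", "tau_dH2",
              "tau_s", "tau_a", "tau_e", "tau_r", "tau_dP1", "tau_dP2",
              "tau_dP3", "mu_q", "mu_S", "P0", "generations", "scenario")) {
    chk(num1(p[[f]]), paste0(f, " must be a single finite number"))
  }
  chk(p$n1 >= 1 && p$n2 >= 1, "patch counts n1, n2 must be >= 1")
  chk(p$r1 > 1 && p$r2 > 1,
      "growth rates r1, r2 must exceed 1 (no positive equilibrium otherwise)")
  chk(p$K1 > 0 && p$K2 > 0, "carrying capacities K1, K2 must be positive")
  for (f in c("tau_dH1", "tau_dH2", "tau_s", "tau_a", "tau_e", "tau_r",
              "tau_dP1", "tau_dP2", "tau_dP3")) {
    chk(p[[f]] > 0, paste0(f, " must be strictly positive"))
  }
  chk(p$tau_dP3 > p$tau_dP1,
      "tau_dP3 must exceed tau_dP1 (generalist offspring develop more slowly)")
  chk(p$mu_q >= 0 && p$mu_q <= 1, "mu_q must lie in [0, 1]")
  chk(p$mu_S >= 0 && p$mu_S <= 1, "mu_S must lie in [0, 1]")
  chk(p$scenario %in% c(1L, 2L), "scenario must be 1 or 2")
  chk(p$P0 >= 0, "P0 must be non-negative")
  chk(p$generations >= 1, "generations must be >= 1")
  p
}

#' Parasitoid-free host equilibrium density
#'
#' The Ricker map with per-capita production `r * exp(-H/K)` has the
#' positive fixed point `H* = K * log(r)`, the expected host density in
#' the absence of parasitism. Used for host initialization and as the
#' analytic reference for parasitoid-free runs.
#'
#' @param K Carrying-capacity coefficient (> 0).
#' @param r Maximum per-capita offspring production rate (> 1).
#' @return The equilibrium host count `K * log(r)` (not rounded).
#' @examples
#' equilibrium_density(1000, 4)  # 1386.294
#' @export
equilibrium_density <- function(K, r) {
  if (any(r <= 1)) stop("no positive equilibrium: r must exceed 1",
                        call. = FALSE)
  if (any(K <= 0)) stop("K must be positive", call. = FALSE)
  K * log(r)
}

#' Generalist developmental efficiency
#'
#' The ratio `tau_dP1 / tau_dP3` labelling how efficient generalist
#' offspring development is relative to specialists (1 would be no cost;
#' smaller is a steeper trade-off).
#'
#' @param p A `"trap_params"` object.
#' @return A single number in (0, 1).
#' @export
generalist_efficiency <- function(p) {
  stopifnot(inherits(p, "trap_params"))
  p$tau_dP1 / p$tau_dP3
}

#' Read a parameter configuration from a YAML file
#'
#' The file is a flat key/value YAML document whose keys are the argument
#' names of [trap_params()]; keys not present keep their defaults.
#' Additional values passed through `...` override the file (so scripted
#' grid experiments can override a base configuration).
#'
#' @param path Path to a YAML file.
#' @param ... Named overrides, as in [trap_params()].
#' @return A validated `"trap_params"` object.
#' @export
read_params <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must be a mapping of parameter names",
                           call. = FALSE)
  known <- names(formals(trap_params))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown parameter(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  vals[names(list(...))] <- list(...)
  do.call(trap_params, vals)
}

#' @export
print.trap_params <- function(x, ...) {
  cat("2-host/1-parasitoid model parameters\n")
  cat(sprintf("  scenario %d (%s)\n", x$scenario,
              if (x$scenario == 1L) "incompatible attack leaves host unharmed"
              else "incompatible attack kills host (non-reproductive mortality)"))
  cat(sprintf("  hosts:      n = (%d, %d) patches, r = (%g, %g), K = (%g, %g), tau_dH = (%g, %g)\n",
              x$n1, x$n2, x$r1, x$r2, x$K1, x$K2, x$tau_dH1, x$tau_dH2))
  cat(sprintf("  foraging:   tau_s = %g, tau_a = %g, tau_e = %g, tau_r = %g\n",
              x$tau_s, x$tau_a, x$tau_e, x$tau_r))
  cat(sprintf("  develop.:   tau_dP = (%g, %g, %g)  [generalist efficiency %.3f]\n",
              x$tau_dP1, x$tau_dP2, x$tau_dP3, generalist_efficiency(x)))
  cat(sprintf("  mutation:   mu_q = %g, mu_S = %g\n", x$mu_q, x$mu_S))
  cat(sprintf("  run:        P0 = %d, generations = %d, seed = %d\n",
              x$P0, x$generations, x$seed))
  invisible(x)
}

#' Experiment design: a set of parameter variants with replication
#'
#' Bundles a list of parameter variants with a replicate count for
#' [trap_grid()]. Variant labels must be unique.
#'
#' @param variants Named list of `"trap_params"` objects (names are the
#'   variant labels; unnamed lists are labelled `variant1`, ...).
#' @param replicates Replicates per variant (>= 1).
#' @param label Optional label for the experiment (used in output paths).
#' @return An object of class `"trap_design"`.
#' @export
experiment_design <- function(variants, replicates = 30L, label = "experiment") {
  if (inherits(variants, "trap_params")) variants <- list(variants)
  stopifnot(is.list(variants), length(variants) >= 1L)
  lapply(variants, validate_parameters)
  if (is.null(names(variants)) || any(names(variants) == ""))
    names(variants) <- paste0("variant", seq_along(variants))
  if (anyDuplicated(names(variants)))
    stop("variant labels must be unique", call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  structure(list(variants = variants, replicates = replicates, label = label),
            class = "trap_design")
}
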