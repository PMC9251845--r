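#' Draw a patch search time
#'
#' Searching parasitoids locate host patches at the constant rate
#' `1/tau_s`, so the waiting time to the next candidate patch is
#' exponential with mean `tau_s`. The process is memoryless: after a
#' patch rejection or departure the search time is simply redrawn.
#'
#' @param tau_s Mean search time (> 0).
#' @param n Number of draws.
#' @return Vector of waiting times.
#' @export
sample_search_time <- function(tau_s, n = 1L) {
  stopifnot(tau_s > 0)
  stats::rexp(n, rate = 1 / tau_s)
}

#' Choose a candidate patch uniformly
#'
#' Searching parasitoids move randomly, so the located patch is uniform
#' over all patches regardless of their contents.
#'
#' @param layout Integer vector of patch species (see [patch_layout()]).
#' @param n Number of draws.
#' @return Patch id(s), indices into `layout`.
#' @export
choose_patch <- function(layout, n = 1L) {
  stopifnot(length(layout) >= 1L)
  sample.int(length(layout), n, replace = TRUE)
}

#' Probability of rejecting a located patch
#'
#' The host-preference trait `q` in `[-1, +1]` sets the rejection
#' probability: `max(0, -q)` for a species-1 patch and `max(0, +q)` for a
#' species-2 patch. `q = 0` accepts everything (random host searching);
#' `q = +1` and `q = -1` exclusively accept patches of host 1 and host 2
#' respectively.
#'
#' @param q Preference value(s) in `[-1, 1]`.
#' @param species Species of the located patch (1 or 2; recycled).
#' @return Rejection probability/ies in `[0, 1]`.
#' @export
rejection_probability <- function(q, species) {
  if (any(q < -1 | q > 1)) stop("q must lie in [-1, 1]", call. = FALSE)
  if (!all(species %in% c(1L, 2L))) stop("species must be 1 or 2",
                                         call. = FALSE)
  ifelse(species == 1L, pmax(0, -q), pmax(0, q))
}

#' Probability that the next accepted patch holds host species 1
#'
#' Closed form for the search-reject-repeat loop: with acceptance
#' probabilities `a1 = 1 - max(0, -q)` and `a2 = 1 - max(0, q)` the next
#' accepted patch is of species 1 with probability
#' `n1 * a1 / (n1 * a1 + n2 * a2)`. Serves as the analytic oracle for the
#' engine's patch-selection behaviour.
#'
#' @param q Preference value(s) in `[-1, 1]`.
#' @param n1,n2 Patch counts per species.
#' @return Probability/ies that the next accepted patch is species 1.
#' @export
accepted_patch_species_probability <- function(q, n1, n2) {
  if (any(q < -1 | q > 1)) stop("q must lie in [-1, 1]", call. = FALSE)
  a1 <- 1 - pmax(0, -q)
  a2 <- 1 - pmax(0, q)
  n1 * a1 / (n1 * a1 + n2 * a2)
}

#' Draw the next host encounter in a patch
#'
#' Each of the `m` encounterable hosts in the patch is met as an
#' independent Poisson process with per-host mean interval `tau_e`; their
#' superposition gives the parasitoid's next encounter after an
#' exponential wait with mean `tau_e / m`, with the encountered host
#' uniform among the `m`. With `m = 0` no encounter ever occurs. The
#' draw is memoryless and is redrawn after every encounter and whenever
#' `m` changes (a host dies).
#'
#' @param m Number of encounterable hosts in the patch.
#' @param tau_e Mean per-host encounter interval (> 0).
#' @return `NULL` if `m == 0`; otherwise a list with `wait` (exponential
#'   waiting time) and `host` (index in `1:m`, uniform).
#' @export
next_encounter <- function(m, tau_e) {
  stopifnot(m >= 0, tau_e > 0)
  if (m == 0L) return(NULL)
  list(wait = stats::rexp(1, rate = m / tau_e),
       host = sample.int(m, 1L))
}

#' Create a fresh within-patch visit state
#'
#' Per-visit memory of one foraging female: the set of host individuals
#' already encountered this visit, the eggs laid this visit (reproductive
#' investment), and the anchor of the patch-abandonment clock. The clock
#' starts at patch entry, so an empty patch is abandoned `tau_a` after
#' arrival.
#'
#' @param entry_time Time of patch entry.
#' @return A list with `encountered` (empty integer vector),
#'   `investment` (0) and `last_encounter_time` (= `entry_time`).
#' @export
new_visit_state <- function(entry_time = 0) {
  list(encountered = integer(0), investment = 0L,
       last_encounter_time = entry_time)
}

#' Decide whether a foraging female stays in or leaves the patch
#'
#' A female leaves the patch when she encounters the same host individual
#' for the second time during the current visit (no additional
#' oviposition occurs on that second encounter), or when `tau_a` time
#' units have elapsed since her last encounter (since patch entry if
#' there has been none).
#'
#' @param visit A visit state (see [new_visit_state()]).
#' @param event A list with `type` (`"encounter"` or `"timeout"`), `time`,
#'   and for encounters `host` (host id).
#' @param tau_a Patch-abandonment threshold.
#' @return `"leave"` or `"stay"`.
#' @export
leave_patch_decision <- function(visit, event, tau_a) {
  stopifnot(event$type %in% c("encounter", "timeout"))
  if (event$type == "timeout") {
    if (event$time - visit$last_encounter_time >= tau_a) return("leave")
    return("stay")
  }
  if (event$host %in% visit$encountered) "leave" else "stay"
}

#' Draw the post-visit recovery time
#'
#' After leaving a patch a female recuperates for the sum of `k`
#' independent exponential waiting times with mean `tau_r` each, one per
#' unit of reproductive investment spent during the visit (a
#' Gamma(`k`, scale `tau_r`) draw); zero if she laid no eggs. Search
#' resumes only after recovery.
#'
#' @param k Reproductive investment of the visit (eggs laid, >= 0).
#' @param tau_r Mean recovery time per unit investment (> 0).
#' @param n Number of draws.
#' @return Recovery time(s).
#' @export
sample_recovery_time <- function(k, tau_r, n = 1L) {
  stopifnot(k >= 0, tau_r > 0)
  if (k == 0L) return(rep(0, n))
  stats::rgamma(n, shape = k, scale = tau_r)
}
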