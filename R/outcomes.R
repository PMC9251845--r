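#' Construct a single host individual
#'
#' List representation of one developing host, used by the operation-level
#' interface ([lay_egg()], [resolve_host_fate()]). The generation engine
#' keeps the same state in columnar form for speed.
#'
#' @param species Host species (1 or 2).
#' @param maturation_time End of the sensitive period, from generation
#'   start.
#' @param patch Patch id.
#' @return A list with fields `species`, `patch`, `maturation_time`,
#'   `eggs` (empty list) and `fate` (`"unresolved"`).
#' @export
host_individual <- function(species, maturation_time, patch = 1L) {
  stopifnot(species %in% c(1L, 2L), maturation_time > 0)
  list(species = as.integer(species), patch = as.integer(patch),
       maturation_time = maturation_time, eggs = list(),
       fate = "unresolved")
}

#' Lay an egg in a vulnerable host
#'
#' Creates the egg record for an oviposition at time `t`: the development
#' completion time is `t` plus an exponential draw whose mean depends
#' only on the mother's strategy ([development_mean()]); compatibility
#' follows the mother's strategy and the host species; and whether the
#' egg *qualifies* to decide the host's fate depends on the scenario
#' (scenario 1: only compatible eggs qualify, incompatible eggs are inert
#' from laying; scenario 2: every egg qualifies, so an incompatible egg
#' can kill the host without yielding offspring). Reproductive investment
#' is paid by the mother either way -- she cannot tell an incompatible
#' host.
#'
#' @param host A host individual (see [host_individual()]); must be
#'   vulnerable at `t` (alive, fate unresolved, `t < maturation_time`).
#' @param mother_q,mother_S The mother's genotype.
#' @param t Oviposition time.
#' @param p A `"trap_params"` object (development means and scenario).
#' @return The host with the new egg appended to `host$eggs`. Each egg is
#'   a list with `parent_q`, `parent_S`, `lay_time`, `completion_time`,
#'   `compatible`, `qualifies`.
#' @export
lay_egg <- function(host, mother_q, mother_S, t, p) {
  stopifnot(inherits(p, "trap_params"))
  if (!identical(host$fate, "unresolved") || t >= host$maturation_time)
    stop("cannot oviposit in a non-vulnerable host", call. = FALSE)
  compatible <- is_compatible(mother_S, host$species)
  egg <- list(parent_q = mother_q,
              parent_S = as.integer(mother_S),
              lay_time = t,
              completion_time = t + stats::rexp(1, rate = 1 / development_mean(mother_S, p)),
              compatible = compatible,
              qualifies = if (p$scenario == 2L) TRUE else compatible)
  host$eggs[[length(host$eggs) + 1L]] <- egg
  host
}

#' Resolve the fate of a host from its eggs
#'
#' The host's fate is decided by the race between its maturation and the
#' earliest *qualifying* egg completion `T*`. If `T* < maturation_time`
#' the host dies at `T*`: when the deciding egg is compatible the kill is
#' reproductive and exactly one parasitoid offspring is created (genotype
#' drawn by [make_offspring_genotype()] from the deciding egg's parent);
#' when it is incompatible (possible only in scenario 2) the kill is
#' non-reproductive and no offspring emerges. If the host matures first
#' it survives and every egg it carries is inviable. All non-deciding
#' eggs are always inviable (solitary parasitoid). A later-laid egg can
#' be the deciding one if it completes development earlier.
#'
#' @param host A host individual with unresolved fate.
#' @param p A `"trap_params"` object.
#' @return A list with `fate` (`"survived"`, `"killed_reproductive"` or
#'   `"killed_nonreproductive"`), `time` (death or maturation time) and
#'   `offspring` (a one-row data.frame with `q`, `S`, or `NULL`).
#' @export
resolve_host_fate <- function(host, p) {
  stopifnot(inherits(p, "trap_params"))
  if (!identical(host$fate, "unresolved"))
    stop("host fate already resolved", call. = FALSE)
  t_star <- Inf
  deciding <- NULL
  for (egg in host$eggs) {
    if (isTRUE(egg$qualifies) && egg$completion_time < t_star) {
      t_star <- egg$completion_time
      deciding <- egg
    }
  }
  if (t_star < host$maturation_time) {
    if (deciding$compatible) {
      list(fate = "killed_reproductive", time = t_star,
           offspring = make_offspring_genotype(deciding$parent_q,
                                               deciding$parent_S, p))
    } else {
      list(fate = "killed_nonreproductive", time = t_star, offspring = NULL)
    }
  } else {
    list(fate = "survived", time = host$maturation_time, offspring = NULL)
  }
}

#' Closed-form single-attack kill probability
#'
#' For one qualifying egg laid while the host is vulnerable, the host's
#' remaining sensitive time is again exponential with mean `tau_dH`
#' (memorylessness), so the probability that the egg completes first is
#' `tau_dH / (tau_dH + tau_dP)`. Analytic oracle for the
#' development-versus-maturation race.
#'
#' @param tau_dP Mean egg development time.
#' @param tau_dH Mean host sensitive period.
#' @return Kill probability/ies.
#' @export
single_attack_success_probability <- function(tau_dP, tau_dH) {
  stopifnot(all(tau_dP > 0), all(tau_dH > 0))
  tau_dH / (tau_dH + tau_dP)
}
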