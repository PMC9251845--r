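#' Physiological compatibility of a parasitization strategy with a host
#'
#' Strategy 1 and 2 are specialists compatible only with host species 1
#' and 2 respectively; strategy 3 is a generalist compatible with both.
#' Only a compatible egg can complete development and emerge.
#'
#' @param S Parasitization strategy, in `{1, 2, 3}` (vectorized).
#' @param species Host species, in `{1, 2}` (vectorized, recycled).
#' @return Logical vector: `TRUE` where the interaction is compatible.
#' @export
is_compatible <- function(S, species) {
  if (!all(S %in% c(1L, 2L, 3L))) stop("S must be in {1, 2, 3}", call. = FALSE)
  if (!all(species %in% c(1L, 2L))) stop("species must be 1 or 2",
                                         call. = FALSE)
  S == species | S == 3L
}

#' Mean development time of an egg, by the mother's strategy
#'
#' Egg development time is exponential with a mean that depends only on
#' the strategy of the parasitoid parent: `tau_dP1`/`tau_dP2` for
#' specialist mothers, the slower `tau_dP3` for generalists. It does not
#' depend on the host species or on compatibility (incompatible eggs in
#' the killing scenario develop at the same "fast" specialist rate, they
#' just never yield a viable adult).
#'
#' @param S_parent Strategy of the mother, in `{1, 2, 3}` (vectorized).
#' @param p A `"trap_params"` object.
#' @return Mean development time(s).
#' @export
development_mean <- function(S_parent, p) {
  stopifnot(inherits(p, "trap_params"))
  if (!all(S_parent %in% c(1L, 2L, 3L)))
    stop("S_parent must be in {1, 2, 3}", call. = FALSE)
  c(p$tau_dP1, p$tau_dP2, p$tau_dP3)[S_parent]
}

#' Mutate the host-preference trait
#'
#' With probability `mu_q` per reproductive event the offspring's
#' preference becomes `q_parent + dq` with `dq` a standard-normal draw,
#' clamped to the trait range `[-1, +1]`; otherwise it is inherited
#' unchanged (clonal reproduction).
#'
#' @param q_parent Parental preference value(s) in `[-1, 1]` (vectorized).
#' @param mu_q Mutation probability per reproductive event.
#' @return Offspring preference value(s).
#' @export
mutate_preference <- function(q_parent, mu_q) {
  if (any(q_parent < -1 | q_parent > 1))
    stop("q_parent must lie in [-1, 1]", call. = FALSE)
  n <- length(q_parent)
  if (n == 0L || mu_q <= 0) return(q_parent)
  hit <- stats::runif(n) < mu_q
  if (any(hit)) {
    dq <- stats::rnorm(sum(hit))
    q_parent[hit] <- pmin(1, pmax(-1, q_parent[hit] + dq))
  }
  q_parent
}

#' Mutate the parasitization strategy
#'
#' With probability `mu_S` per reproductive event the strategy changes
#' along the allowed transitions: either specialist mutates to the
#' generalist with probability 1, and the generalist mutates to each
#' specialist with probability 1/2. A specialist can never become the
#' other specialist in a single step.
#'
#' @param S_parent Parental strategy value(s) in `{1, 2, 3}` (vectorized).
#' @param mu_S Mutation probability per reproductive event.
#' @return Offspring strategy value(s).
#' @export
mutate_strategy <- function(S_parent, mu_S) {
  if (!all(S_parent %in% c(1L, 2L, 3L)))
    stop("S_parent must be in {1, 2, 3}", call. = FALSE)
  S_parent <- as.integer(S_parent)
  n <- length(S_parent)
  if (n == 0L || mu_S <= 0) return(S_parent)
  hit <- stats::runif(n) < mu_S
  if (any(hit)) {
    from <- S_parent[hit]
    to <- ifelse(from == 3L,
                 ifelse(stats::runif(length(from)) < 0.5, 1L, 2L),
                 3L)
    S_parent[hit] <- as.integer(to)
  }
  S_parent
}

#' Strategy-mutation transition matrix
#'
#' The 3x3 matrix of transition probabilities conditional on a mutation
#' occurring; row = parental strategy, column = offspring strategy.
#' Its stationary distribution is (1/4, 1/4, 1/2).
#'
#' @return A 3x3 numeric matrix with rows summing to 1.
#' @export
strategy_transition_matrix <- function() {
  matrix(c(0, 0, 1,
           0, 0, 1,
           0.5, 0.5, 0),
         nrow = 3, byrow = TRUE,
         dimnames = list(from = 1:3, to = 1:3))
}

#' Offspring genotype under clonal inheritance with mutation
#'
#' Applies [mutate_preference()] and [mutate_strategy()] independently to
#' the parental genotype; called once per emerging parasitoid offspring.
#' Mutation acts at offspring creation: the egg's development time and
#' compatibility are governed by the parent's genotype (maternal
#' physiology), and the possibly mutated genotype is expressed only from
#' the offspring's own adulthood.
#'
#' @param q_parent,S_parent Parental trait vectors (one element per
#'   reproductive event; equal lengths).
#' @param p A `"trap_params"` object (supplies `mu_q` and `mu_S`).
#' @return A data.frame with columns `q` and `S`, one row per offspring.
#' @export
make_offspring_genotype <- function(q_parent, S_parent, p) {
  stopifnot(inherits(p, "trap_params"), length(q_parent) == length(S_parent))
  data.frame(q = mutate_preference(q_parent, p$mu_q),
             S = mutate_strategy(S_parent, p$mu_S))
}
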