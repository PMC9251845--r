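#' Run one parasitoid generation
#'
#' Processes the continuous-time foraging/oviposition/development event
#' race for one discrete generation: time-limited females cycle through
#' patch search, within-patch host encounters and post-visit recovery,
#' eggs race the hosts' sensitive periods, and every host resolves to
#' survived / killed (reproductively or not). The generation ends when no
#' vulnerable host remains anywhere; pending parasitoid events are then
#' discarded (no further reproduction is possible). Offspring genotypes
#' are drawn from the deciding eggs' parents via
#' [make_offspring_genotype()]; emergence timing within the generation is
#' irrelevant because offspring act only in the next generation.
#'
#' @param hosts A data.frame with columns `species`, `patch`,
#'   `maturation_time` (see [sample_maturation_times()]).
#' @param parasitoids A data.frame with columns `q` and `S`, one row per
#'   foraging female (may have zero rows).
#' @param p A `"trap_params"` object.
#' @return A list with:
#'   * `fate`: character vector per host (`"survived"`,
#'     `"killed_reproductive"`, `"killed_nonreproductive"`);
#'   * `attacked`: logical per host (received at least one egg);
#'   * `offspring`: data.frame `q`, `S` of the next parasitoid
#'     generation (already mutated);
#'   * `tally`: per-species kill/egg bookkeeping (`spawned`, `survived`,
#'     `killed_reproductive`, `killed_nonreproductive`, `eggs_laid`,
#'     each length 2, plus scalar `emerged`).
#' @export
run_generation <- function(hosts, parasitoids, p) {
  stopifnot(inherits(p, "trap_params"),
            all(c("species", "patch", "maturation_time") %in% names(hosts)),
            all(c("q", "S") %in% names(parasitoids)))
  layout <- patch_layout(p)
  res <- .sim_generation_cpp(
    as.integer(hosts$species), as.integer(hosts$patch),
    as.numeric(hosts$maturation_time),
    as.numeric(parasitoids$q), as.integer(parasitoids$S),
    length(layout), layout,
    p$tau_s, p$tau_a, p$tau_e, p$tau_r,
    c(p$tau_dP1, p$tau_dP2, p$tau_dP3), p$scenario,
    p$matured_encounterable)

  fate <- c("survived", "killed_reproductive",
            "killed_nonreproductive")[res$fate]
  offspring <- make_offspring_genotype(res$off_parent_q, res$off_parent_S, p)

  by_species <- function(keep) {
    c(sum(keep & hosts$species == 1L), sum(keep & hosts$species == 2L))
  }
  tally <- list(
    spawned = by_species(TRUE),
    survived = by_species(fate == "survived"),
    killed_reproductive = by_species(fate == "killed_reproductive"),
    killed_nonreproductive = by_species(fate == "killed_nonreproductive"),
    eggs_laid = as.integer(res$eggs_laid),
    emerged = nrow(offspring))
  list(fate = fate, attacked = res$attacked == 1L,
       offspring = offspring, tally = tally)
}

#' Simulate one replicate of the evolutionary experiment
#'
#' Runs the full individual-based simulation: hosts are initialized at
#' their parasitoid-free equilibrium, the founding parasitoid population
#' consists of `P0` females pre-adapted to the original host (genotype
#' `q = 0`, `S = 1`), and generations iterate for `p$generations` steps.
#' Each generation regenerates hosts by the stochastic Ricker process
#' ([spawn_offspring()]), runs the foraging/development race
#' ([run_generation()]), and replaces the parasitoid population by the
#' emerged offspring. If parasitoids go extinct the host-only dynamics
#' continue to the horizon so the time series stays rectangular.
#'
#' @param p A `"trap_params"` object.
#' @param replicate_seed Seed for this replicate (defaults to `p$seed`).
#' @return An object of class `"trap_sim"`: a list with `records` (one
#'   data.frame row per generation, see Details), `params`, `seed` and
#'   `extinction_generation` (`NA` if parasitoids persist).
#'
#' @details Record columns: `generation`; `H1`, `H2` (host counts after
#' parasitism); `P` (adult parasitoids foraging that generation);
#' strategy frequencies `freq_S1`..`freq_S3` and class counts
#' `n_S1`..`n_S3`; `mean_q`, `sd_q` overall and `mean_q_S*`, `sd_q_S*`
#' within class (`NA` for empty/singleton classes -- class counts are
#' reported so consumers can see when a per-class mean rests on a handful
#' of rare genotypes); per-species `spawned*`, `survived*`, `killed_repro*`,
#' `killed_nonrepro*`, `eggs*`; and `emerged`. Frequencies are `NA` when
#' `P = 0`.
#' @export
trap_sim <- function(p, replicate_seed = p$seed) {
  stopifnot(inherits(p, "trap_params"))
  set.seed(as.integer(replicate_seed))

  init <- initialize_hosts(p)
  hosts <- init$hosts
  parasitoids <- data.frame(q = rep(0, p$P0), S = rep(1L, p$P0))
  extinction <- NA_integer_

  records <- vector("list", p$generations)
  for (g in seq_len(p$generations)) {
    gen <- run_generation(hosts, parasitoids, p)
    records[[g]] <- generation_record(g, parasitoids, gen$tally)
    if (nrow(parasitoids) == 0L && is.na(extinction)) extinction <- g
    parasitoids <- gen$offspring
    if (g < p$generations) {
      s1 <- spawn_offspring(gen$tally$survived[1], p, 1L)
      s2 <- spawn_offspring(gen$tally$survived[2], p, 2L)
      hosts <- rbind(
        sample_maturation_times(s1, p$tau_dH1, 1L, seq_len(p$n1)),
        sample_maturation_times(s2, p$tau_dH2, 2L, p$n1 + seq_len(p$n2)))
    }
  }
  structure(list(records = do.call(rbind, records), params = p,
                 seed = as.integer(replicate_seed),
                 extinction_generation = extinction),
            class = "trap_sim")
}

# one GenerationRecord row; adults = the females that foraged this step
generation_record <- function(g, adults, tally) {
  P <- nrow(adults)
  cls_mean <- function(s) {
    qq <- adults$q[adults$S == s]
    if (length(qq) == 0L) NA_real_ else mean(qq)
  }
  cls_sd <- function(s) {
    qq <- adults$q[adults$S == s]
    if (length(qq) < 2L) NA_real_ else stats::sd(qq)
  }
  data.frame(
    generation = g,
    H1 = tally$survived[1], H2 = tally$survived[2], P = P,
    freq_S1 = if (P > 0) mean(adults$S == 1L) else NA_real_,
    freq_S2 = if (P > 0) mean(adults$S == 2L) else NA_real_,
    freq_S3 = if (P > 0) mean(adults$S == 3L) else NA_real_,
    mean_q = if (P > 0) mean(adults$q) else NA_real_,
    sd_q = if (P > 1) stats::sd(adults$q) else NA_real_,
    mean_q_S1 = cls_mean(1L), mean_q_S2 = cls_mean(2L),
    mean_q_S3 = cls_mean(3L),
    sd_q_S1 = cls_sd(1L), sd_q_S2 = cls_sd(2L), sd_q_S3 = cls_sd(3L),
    n_S1 = sum(adults$S == 1L), n_S2 = sum(adults$S == 2L),
    n_S3 = sum(adults$S == 3L),
    spawned1 = tally$spawned[1], spawned2 = tally$spawned[2],
    survived1 = tally$survived[1], survived2 = tally$survived[2],
    killed_repro1 = tally$killed_reproductive[1],
    killed_repro2 = tally$killed_reproductive[2],
    killed_nonrepro1 = tally$killed_nonreproductive[1],
    killed_nonrepro2 = tally$killed_nonreproductive[2],
    eggs1 = tally$eggs_laid[1], eggs2 = tally$eggs_laid[2],
    emerged = tally$emerged)
}

#' Deterministic per-replicate seed derivation
#'
#' Derives the seed of replicate `rep` of variant `variant` from the
#' master seed, so any single replicate of a grid can be reproduced in
#' isolation. Kept below 2^31 - 1 (R integers are 32-bit).
#'
#' @param master Master seed (integer).
#' @param variant Variant index (1-based).
#' @param rep Replicate index (1-based).
#' @return An integer seed.
#' @export
replicate_seed <- function(master, variant, rep) {
  as.integer((as.double(master) + 1000003 * (variant - 1) + rep) %%
               2147483647)
}

#' Run a grid of experimental variants with replication
#'
#' Runs every variant x replicate cell of an [experiment_design()] with
#' seeds derived by [replicate_seed()] from the master seed, and
#' aggregates final-generation strategy frequencies as mean +/- SE
#' across replicates (SE = sd / sqrt(n); `NA` with a single replicate).
#'
#' @param design A `"trap_design"` object.
#' @param master_seed Master seed (defaults to the first variant's seed).
#' @param keep_records Keep the full per-replicate `"trap_sim"` objects
#'   (memory heavy for long runs); otherwise only final records are kept.
#' @return An object of class `"trap_grid"`: list with `summary` (one row
#'   per variant), `finals` (one row per replicate: final-generation
#'   record plus variant/replicate/seed/outcome columns), `results`
#'   (list of `"trap_sim"`, if kept) and `design`.
#' @export
trap_grid <- function(design, master_seed = design$variants[[1]]$seed,
                      keep_records = FALSE) {
  stopifnot(inherits(design, "trap_design"))
  labels <- names(design$variants)
  finals <- list()
  results <- if (keep_records) list() else NULL
  for (v in seq_along(design$variants)) {
    p <- design$variants[[v]]
    for (rep in seq_len(design$replicates)) {
      sd_vr <- replicate_seed(master_seed, v, rep)
      sim <- trap_sim(p, sd_vr)
      fin <- sim$records[nrow(sim$records), , drop = FALSE]
      fin$variant <- labels[v]
      fin$replicate <- rep
      fin$seed <- sd_vr
      fin$outcome <- classify_outcome(fin)
      fin$extinct <- !is.na(sim$extinction_generation)
      finals[[length(finals) + 1L]] <- fin
      if (keep_records)
        results[[paste0(labels[v], ".rep", rep)]] <- sim
    }
  }
  finals <- do.call(rbind, finals)
  structure(list(summary = summarize_grid(finals, design),
                 finals = finals, results = results, design = design),
            class = "trap_grid")
}

summarize_grid <- function(finals, design) {
  labels <- names(design$variants)
  rows <- lapply(seq_along(labels), function(v) {
    p <- design$variants[[v]]
    f <- finals[finals$variant == labels[v], , drop = FALSE]
    n <- nrow(f)
    se <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
    data.frame(
      variant = labels[v], scenario = p$scenario, tau_s = p$tau_s,
      generalist_efficiency = generalist_efficiency(p),
      mu_q = p$mu_q, mu_S = p$mu_S, replicates = n,
      mean_freq_S1 = mean(f$freq_S1, na.rm = TRUE),
      se_freq_S1 = se(f$freq_S1),
      mean_freq_S2 = mean(f$freq_S2, na.rm = TRUE),
      se_freq_S2 = se(f$freq_S2),
      mean_freq_S3 = mean(f$freq_S3, na.rm = TRUE),
      se_freq_S3 = se(f$freq_S3),
      mean_q_S1 = mean(f$mean_q_S1, na.rm = TRUE),
      mean_q_S2 = mean(f$mean_q_S2, na.rm = TRUE),
      mean_q_S3 = mean(f$mean_q_S3, na.rm = TRUE),
      extinction_fraction = mean(f$extinct))
  })
  do.call(rbind, rows)
}
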