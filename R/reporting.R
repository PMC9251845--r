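#' Classify the final-generation outcome of a replicate
#'
#' Labels which parasitization strategy dominates at the end of a run:
#' `"extinct"` if no parasitoid is left, otherwise the strategy class
#' whose frequency exceeds 0.5 (`"specialist1"`, `"specialist2"`,
#' `"generalist"`), or `"polymorphic"` when none does.
#'
#' @param record A one-row data.frame with columns `P`, `freq_S1`,
#'   `freq_S2`, `freq_S3` (typically the final row of
#'   `trap_sim()$records`).
#' @return A single character label.
#' @export
classify_outcome <- function(record) {
  stopifnot(nrow(record) == 1L)
  if (record$P == 0) return("extinct")
  f <- c(record$freq_S1, record$freq_S2, record$freq_S3)
  if (max(f) > 0.5)
    c("specialist1", "specialist2", "generalist")[which.max(f)]
  else "polymorphic"
}

#' Write a replicate time series to CSV with a provenance sidecar
#'
#' Writes the per-generation records as an RFC-4180 CSV ('.' decimal,
#' UTF-8, header row, fixed column order as documented in [trap_sim()]),
#' plus a JSON sidecar (same path with extension `.json`) containing the
#' full parameter set and the replicate seed so any file can be
#' regenerated exactly.
#'
#' @param result A `"trap_sim"` object.
#' @param path Output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_timeseries <- function(result, path) {
  stopifnot(inherits(result, "trap_sim"))
  utils::write.csv(result$records, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  prov <- unclass(result$params)
  prov$replicate_seed <- result$seed
  jsonlite::write_json(prov, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read back a time series written by [write_timeseries()]
#'
#' @param path CSV path.
#' @return A `"trap_sim"` object (records, params and seed restored from
#'   the CSV and its sidecar).
#' @export
read_timeseries <- function(path) {
  records <- utils::read.csv(path)
  for (j in seq_along(records)) {
    if (is.logical(records[[j]])) records[[j]] <- as.numeric(records[[j]])
  }
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  prov <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  seed <- prov$replicate_seed
  prov$replicate_seed <- NULL
  p <- do.call(trap_params, prov)
  ext <- which(records$P == 0)
  structure(list(records = records, params = p, seed = as.integer(seed),
                 extinction_generation =
                   if (length(ext)) ext[1] else NA_integer_),
            class = "trap_sim")
}

#' @export
print.trap_sim <- function(x, ...) {
  r <- x$records
  fin <- r[nrow(r), ]
  cat(sprintf("Host-parasitoid trap simulation: %d generations, seed %d\n",
              nrow(r), x$seed))
  cat(sprintf("  scenario %d, tau_s = %g, generalist efficiency %.3f, mu_q = %g, mu_S = %g\n",
              x$params$scenario, x$params$tau_s,
              generalist_efficiency(x$params), x$params$mu_q, x$params$mu_S))
  if (!is.na(x$extinction_generation)) {
    cat(sprintf("  parasitoids extinct at generation %d\n",
                x$extinction_generation))
  } else {
    cat(sprintf("  final: P = %d (S1 %.2f, S2 %.2f, S3 %.2f), H1 = %d, H2 = %d\n",
                fin$P, fin$freq_S1, fin$freq_S2, fin$freq_S3, fin$H1, fin$H2))
    cat(sprintf("  outcome: %s\n", classify_outcome(fin)))
  }
  invisible(x)
}

#' @export
summary.trap_sim <- function(object, ...) {
  r <- object$records
  fin <- r[nrow(r), ]
  out <- list(
    generations = nrow(r),
    outcome = classify_outcome(fin),
    extinction_generation = object$extinction_generation,
    final = fin,
    mean_hosts = c(H1 = mean(r$H1), H2 = mean(r$H2)),
    mean_P = mean(r$P),
    total_nonreproductive_kills = sum(r$killed_nonrepro1 +
                                        r$killed_nonrepro2))
  class(out) <- "summary.trap_sim"
  out
}

#' @export
print.summary.trap_sim <- function(x, ...) {
  cat(sprintf("%d generations; outcome: %s\n", x$generations, x$outcome))
  if (!is.na(x$extinction_generation))
    cat(sprintf("parasitoids extinct at generation %d\n",
                x$extinction_generation))
  cat(sprintf("mean hosts: H1 = %.1f, H2 = %.1f; mean parasitoids: %.1f\n",
              x$mean_hosts[1], x$mean_hosts[2], x$mean_P))
  cat(sprintf("non-reproductive kills over the run: %d\n",
              x$total_nonreproductive_kills))
  fin <- x$final
  cat(sprintf("final strategy frequencies: S1 %.3f, S2 %.3f, S3 %.3f (P = %d)\n",
              fin$freq_S1, fin$freq_S2, fin$freq_S3, fin$P))
  cat(sprintf("final mean preference q: %.3f\n", fin$mean_q))
  invisible(x)
}

#' Plot strategy frequencies and host/parasitoid densities over time
#'
#' Two stacked base-graphics panels: strategy-class frequencies (top) and
#' population densities (bottom).
#'
#' @param x A `"trap_sim"` object.
#' @param ... Passed to `matplot`.
#' @export
plot.trap_sim <- function(x, ...) {
  r <- x$records
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::matplot(r$generation, cbind(r$freq_S1, r$freq_S2, r$freq_S3),
                    type = "l", lty = 1, lwd = 1.5,
                    col = c("firebrick", "steelblue", "grey40"),
                    xlab = "generation", ylab = "strategy frequency",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", bty = "n", lty = 1, lwd = 1.5,
                   col = c("firebrick", "steelblue", "grey40"),
                   legend = c("specialist 1", "specialist 2", "generalist"))
  graphics::matplot(r$generation, cbind(r$H1, r$H2, r$P), type = "l",
                    lty = c(1, 1, 2), lwd = 1,
                    col = c("firebrick", "steelblue", "black"),
                    xlab = "generation", ylab = "individuals")
  graphics::legend("topright", bty = "n", lty = c(1, 1, 2),
                   col = c("firebrick", "steelblue", "black"),
                   legend = c("host 1", "host 2", "parasitoids"))
  invisible(x)
}

#' @export
print.trap_grid <- function(x, ...) {
  cat(sprintf("Grid experiment: %d variant(s) x %d replicate(s)\n",
              length(x$design$variants), x$design$replicates))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write grid outputs: one CSV per replicate plus a summary CSV
#'
#' @param grid A `"trap_grid"` object run with `keep_records = TRUE`
#'   (per-replicate CSVs need the full records; without them only the
#'   summary and finals are written).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "trap_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(grid$results)) {
    for (nm in names(grid$results)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      write_timeseries(grid$results[[nm]], f)
      paths <- c(paths, f)
    }
  }
  fsum <- file.path(dir, "summary.csv")
  utils::write.csv(grid$summary, fsum, row.names = FALSE)
  ffin <- file.path(dir, "finals.csv")
  utils::write.csv(grid$finals, ffin, row.names = FALSE)
  invisible(c(paths, fsum, ffin))
}
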