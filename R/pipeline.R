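#' End-to-end complex detection run
#'
#' Loads (or accepts) a network, builds must-link constraints from either an
#' explicit constraint file/object or by sampling a reference catalog, fits
#' the SSNMTF model, extracts complexes, and — when `out_dir` is given —
#' writes the predicted cover (`complexes.txt`), the objective trace
#' (`trace.tsv`), the fitted factors (optional) and a JSON run manifest
#' recording every parameter, seed and input checksum needed to reproduce
#' the run.
#'
#' @param network a `ppi_network` or a path to an edge-list file.
#' @param weighted when `network` is a path: read edge weights.
#' @param mustlinks a [mustlink()] object or path to a constraint file;
#'   exactly one of `mustlinks` / `reference` may be given (neither means
#'   an unsupervised fit).
#' @param reference a `complex_cover` or catalog path from which
#'   constraints are sampled at `mustlink_fraction`.
#' @param mustlink_fraction fraction of candidate pairs sampled from
#'   `reference` (default 0.1).
#' @param k module budget; default 1000, the customary setting for real
#'   interaction networks (empty modules are pruned at detection).
#' @param alpha must-link weight (default 10).
#' @param mode `"nonoverlap"` or `"overlap"` detection.
#' @param min_size minimum reported complex size (default 3).
#' @param seed integer seed governing sampling and initialization.
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param dump_factors also write `F.tsv` / `G.tsv` (default `FALSE`).
#' @param ... further arguments passed to [ssnmtf()] (`max_iter`,
#'   `rel_tol`, `init`, `symmetrize_G`, ...).
#' @return Invisibly, list with `cover`, `fit`, and the `manifest` list.
#' @export
run_detect <- function(network, weighted = FALSE, mustlinks = NULL,
                       reference = NULL, mustlink_fraction = 0.1, k = 1000,
                       alpha = 10, mode = c("nonoverlap", "overlap"),
                       min_size = 3, seed = 1L, out_dir = NULL,
                       dump_factors = FALSE, ...) {
  mode <- match.arg(mode)
  if (!is.null(mustlinks) && !is.null(reference))
    stop("give either explicit must-links or a reference to sample, not both")
  paths <- list()
  if (is.character(network)) {
    if (!file.exists(network)) stop("network file not found: ", network)
    paths$network <- network
    network <- read_edgelist(network, weighted = weighted)
  }
  if (is.character(mustlinks)) {
    paths$mustlinks <- mustlinks
    mustlinks <- read_mustlinks(mustlinks, alpha = alpha)
  }
  if (is.character(reference)) {
    paths$reference <- reference
    reference <- read_complexes(reference)
  }
  if (!is.null(reference)) {
    reference <- restrict_cover(reference, network, min_size = 3)
    mustlinks <- sample_mustlinks(reference, fraction = mustlink_fraction,
                                  alpha = alpha, seed = seed)
  }
  cm <- if (is.null(mustlinks)) NULL else
    build_constraint_matrices(mustlinks, network, on_missing = "drop")
  k <- min(k, length(network$nodes))
  fit <- ssnmtf(network, cm, k = k, alpha = alpha, seed = seed, ...)
  cover <- predict(fit, mode = mode, min_size = min_size)
  message(sprintf(
    "fit: %d iteration(s), objective %.6g; %d complex(es) of >= %d nodes",
    fit$iterations, fit$objective, length(cover$complexes), min_size))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ssnmtf")),
    parameters = list(k = k, alpha = alpha, mode = mode, min_size = min_size,
                      mustlink_fraction = if (is.null(reference)) NULL
                                          else mustlink_fraction,
                      seed = seed),
    n_nodes = length(network$nodes),
    n_mustlinks = if (is.null(mustlinks)) 0L else nrow(mustlinks$pairs),
    iterations = fit$iterations, converged = fit$converged,
    objective = fit$objective, n_complexes = length(cover$complexes),
    input_md5 = if (length(paths)) as.list(tools::md5sum(unlist(paths)))
                else NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cover(cover, file.path(out_dir, "complexes.txt"))
    utils::write.table(
      data.frame(iteration = seq_along(fit$trace) - 1L, objective = fit$trace),
      file.path(out_dir, "trace.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (dump_factors) {
      write_matrix_tsv(fit$F, rownames(fit$F), colnames(fit$F),
                       file.path(out_dir, "F.tsv"))
      write_matrix_tsv(fit$G, rownames(fit$G), colnames(fit$G),
                       file.path(out_dir, "G.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(cover = cover, fit = fit, manifest = manifest))
}

#' Synthetic benchmark: recovery vs. must-link supply
#'
#' For each replicate and each mixing parameter, generates an LFR-style
#' network with planted modules, then for every must-link fraction samples
#' ground-truth constraints, fits SSNMTF (module budget `k_factor` times
#' the planted module count), extracts modules and scores them against the
#' planted truth — partition NMI under non-overlapping detection,
#' overlapping-cover NMI otherwise.
#'
#' @param mus mixing parameter(s) to sweep.
#' @param fractions must-link fractions to sweep (0 = unsupervised
#'   baseline).
#' @param replicates independently generated networks per `mu`.
#' @param N,ad,d_max,m_min,m_max,on,om LFR parameters, see
#'   [generate_lfr()]; defaults mirror the standard benchmark
#'   configuration (N = 1000, ad = 15, d_max = 50, sizes 20-50).
#' @param mode detection mode, as in [predict.ssnmtf()].
#' @param alpha must-link weight.
#' @param k_factor module budget relative to planted module count
#'   (default 1.5).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param verbose print one line per completed fit.
#' @param ... passed to [ssnmtf()].
#' @return data.frame with one row per (mu, fraction, replicate):
#'   `mu, fraction, replicate, seed, nmi, iterations, objective`, with a
#'   `summary` attribute holding mean and sd of NMI per (mu, fraction).
#' @export
run_benchmark <- function(mus = 0.7, fractions = c(0, 0.03, 0.07),
                          replicates = 10, N = 1000, ad = 15, d_max = 50,
                          m_min = 20, m_max = 50, on = 0, om = 1,
                          mode = c("nonoverlap", "overlap"), alpha = 10,
                          k_factor = 1.5, seed = 1L, verbose = FALSE, ...) {
  mode <- match.arg(mode)
  stopifnot(replicates >= 1)
  rows <- list()
  for (mu in mus) {
    for (r in seq_len(replicates)) {
      rs <- (abs(seed) * 1009L + r * 97L + round(100 * mu)) %% 2147483647L
      sim <- generate_lfr(N = N, ad = ad, d_max = d_max, m_min = m_min,
                          m_max = m_max, mu = mu, on = on, om = om,
                          seed = rs)
      k <- max(2L, round(k_factor * length(sim$truth$complexes)))
      for (fr in fractions) {
        ml <- mustlinks_from_truth(sim$truth, fraction = fr, alpha = alpha,
                                   seed = rs + 1L)
        fit <- ssnmtf(sim$network, if (nrow(ml$pairs)) ml else NULL, k = k,
                      alpha = alpha, seed = rs + 2L, ...)
        nmi <- if (mode == "nonoverlap") {
          nmi_partition(assign_nonoverlapping(fit$F, fit$nodes), sim$truth,
                        universe = fit$nodes)
        } else {
          nmi_cover(predict(fit, mode = "overlap", min_size = 3), sim$truth,
                    universe = fit$nodes)
        }
        if (verbose)
          message(sprintf("mu=%.2f rep=%d fr=%.2f: nmi=%.4f (%d iter)",
                          mu, r, fr, nmi, fit$iterations))
        rows[[length(rows) + 1L]] <-
          data.frame(mu = mu, fraction = fr, replicate = r, seed = rs,
                     nmi = nmi, iterations = fit$iterations,
                     objective = fit$objective)
      }
    }
  }
  out <- do.call(rbind, rows)
  s <- stats::aggregate(nmi ~ mu + fraction, out,
                        function(x) c(mean = mean(x), sd = stats::sd(x)))
  attr(out, "summary") <- do.call(data.frame, s)
  out
}
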