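# LFR-style benchmark generator: power-law degrees and module sizes, a
# tunable mixing parameter mu (fraction of each node's links leaving its
# module), and optional overlapping nodes with multiple memberships.

# sample `n` integers from a truncated continuous power law with density
# x^-gamma on [xmin, xmax], rounded to integers
rpowerlaw_int <- function(n, gamma, xmin, xmax) {
  u <- stats::runif(n)
  x <- if (abs(gamma - 1) < 1e-9) {
    xmin * (xmax / xmin)^u
  } else {
    g1 <- 1 - gamma
    (xmin^g1 + u * (xmax^g1 - xmin^g1))^(1 / g1)
  }
  pmin(pmax(round(x), round(xmin)), xmax)
}

# mean of the rounded truncated power law, by quadrature on the integer grid
powerlaw_mean <- function(gamma, xmin, xmax) {
  xs <- seq(floor(xmin), xmax)
  w <- xs^(-gamma); w[xs < xmin] <- 0
  # continuous-sampling then rounding ~ integrate density around each integer
  lo <- pmax(xs - 0.5, xmin); hi <- pmin(xs + 0.5, xmax)
  g1 <- 1 - gamma
  mass <- ifelse(hi > lo,
                 if (abs(g1) < 1e-9) log(hi / lo) else (hi^g1 - lo^g1) / g1, 0)
  sum(xs * mass) / sum(mass)
}

# pick xmin so that rounded power-law draws on [xmin, xmax] average to `target`
solve_xmin <- function(gamma, xmax, target) {
  f <- function(xm) powerlaw_mean(gamma, xm, xmax) - target
  if (f(1) >= 0) return(1)
  stats::uniroot(f, c(1, xmax - 1e-6), tol = 1e-6)$root
}

# draw module sizes from a truncated power law until their sum is exactly
# `total` membership slots; the last draw is trimmed, with the deficit pushed
# into earlier modules when trimming would violate the minimum size
draw_sizes <- function(total, gamma, m_min, m_max) {
  sizes <- integer(0)
  while (sum(sizes) < total)
    sizes <- c(sizes, rpowerlaw_int(1, gamma, m_min, m_max))
  excess <- sum(sizes) - total
  last <- sizes[length(sizes)]
  if (last - excess >= m_min) {
    sizes[length(sizes)] <- last - excess
  } else {
    sizes <- sizes[-length(sizes)]
    need <- total - sum(sizes)           # < m_min, spread over earlier modules
    i <- 1L
    while (need > 0) {
      room <- m_max - sizes[i]
      add <- min(room, need)
      sizes[i] <- sizes[i] + add
      need <- need - add
      i <- i %% length(sizes) + 1L
      if (i == 1L && all(sizes == m_max) && need > 0)
        sizes <- c(sizes, max(m_min, min(m_max, need)))
    }
  }
  sizes
}

# random pairing of a stub multiset into simple edges; up to `sweeps`
# reshuffles of offending stubs, then residual bad pairs are dropped
pair_stubs <- function(stubs, forbidden = NULL, sweeps = 100) {
  # forbidden: function(a, b) -> logical, extra rejection rule (vectorized)
  if (length(stubs) < 2) return(cbind(integer(0), integer(0)))
  if (length(stubs) %% 2 == 1) stubs <- stubs[-length(stubs)]
  stubs <- sample(stubs)
  ed <- matrix(stubs, ncol = 2, byrow = TRUE)
  for (s in seq_len(sweeps)) {
    a <- pmin(ed[, 1], ed[, 2]); b <- pmax(ed[, 1], ed[, 2])
    bad <- a == b | duplicated(cbind(a, b))
    if (!is.null(forbidden)) bad <- bad | forbidden(a, b)
    if (!any(bad)) break
    # re-shuffle the stubs of bad pairs together with as many random good pairs
    good <- which(!bad)
    mix <- c(which(bad), sample(good, min(length(good), sum(bad))))
    pool <- sample(as.vector(ed[mix, ]))
    ed[mix, ] <- matrix(pool, ncol = 2)
  }
  a <- pmin(ed[, 1], ed[, 2]); b <- pmax(ed[, 1], ed[, 2])
  bad <- a == b | duplicated(cbind(a, b))
  if (!is.null(forbidden)) bad <- bad | forbidden(a, b)
  if (any(bad))
    message(sum(bad), " residual stub pair(s) dropped during wiring")
  cbind(a[!bad], b[!bad])
}

#' Generate an LFR-style benchmark network with planted modules
#'
#' Emulates the standard LFR benchmark family: node degrees follow a
#' truncated power law (exponent `degree_exponent`) with mean close to `ad`
#' and maximum `d_max`; module sizes follow a truncated power law (exponent
#' `size_exponent`) on `[m_min, m_max]`; each node spends a fraction
#' `1 - mu` of its links inside its module(s) and `mu` outside; wiring is a
#' configuration-model stub matching with rejection sweeps against
#' self-loops and multi-edges.  When `on > 0`, exactly `on` randomly chosen
#' nodes belong to `om` modules each (their internal degree split equally
#' among memberships), all other nodes to exactly one.
#'
#' @param N node count.
#' @param ad target average degree.
#' @param d_max maximum degree.
#' @param m_min,m_max module-size bounds.
#' @param mu mixing parameter in `[0, 1]`: fraction of each node's links
#'   leaving its module(s); larger values blur the planted structure.
#' @param on number of overlapping nodes (0 for a partition).
#' @param om memberships per overlapping node.
#' @param degree_exponent,size_exponent power-law exponents (defaults 2 and
#'   1, the customary LFR settings).
#' @param seed integer seed; the full generation is deterministic given it.
#' @return list with `network` (a [ppi_network()], nodes `n1..nN`),
#'   `truth` (the planted [complex_cover()]), and `membership` (list of
#'   module-index vectors per node).
#' @export
generate_lfr <- function(N = 1000, ad = 15, d_max = 50, m_min = 20,
                         m_max = 50, mu = 0.6, on = 0, om = 1,
                         degree_exponent = 2, size_exponent = 1,
                         seed = 1L) {
  stopifnot(m_min <= m_max, m_max <= N, on <= N, om >= 1, mu >= 0, mu <= 1,
            ad <= d_max, ad >= 1)
  if (on == 0) om <- 1
  with_seed(seed, {
    ## degrees
    xmin <- solve_xmin(degree_exponent, d_max, ad)
    deg <- rpowerlaw_int(N, degree_exponent, xmin, d_max)
    for (tries in 1:20) {                     # recenter the realized mean
      if (abs(mean(deg) - ad) / ad < 0.02) break
      xmin <- max(1, xmin * ad / mean(deg))
      deg <- rpowerlaw_int(N, degree_exponent, xmin, d_max)
    }
    # internal degree per membership must fit inside the smallest module
    cap <- if (mu < 1) floor((m_min - 1) * om / (1 - mu)) else d_max
    deg <- pmin(deg, max(cap, 1), d_max)
    if (sum(deg) %% 2 == 1) deg[which.min(deg)] <- deg[which.min(deg)] + 1

    ## module sizes over N + on*(om-1) membership slots
    slots <- N + on * (om - 1)
    if (slots < m_min) stop("infeasible: fewer membership slots than m_min")
    sizes <- draw_sizes(slots, size_exponent, m_min, m_max)
    n_mod <- length(sizes)
    if (on > 0 && n_mod < om)
      stop("infeasible: fewer modules than memberships per overlapping node")

    ## memberships
    membership <- NULL
    for (attempt in 1:50) {
      free <- sizes
      memb <- vector("list", N)
      ovl <- sample.int(N, on)
      need <- rep(1L, N); need[ovl] <- om
      ord <- sample.int(N)                     # fill in random node order
      ord <- ord[order(-need[ord])]            # multi-membership nodes first
      ok <- TRUE
      for (i in ord) {
        open <- which(free > 0)
        if (length(open) < need[i]) { ok <- FALSE; break }
        pick <- if (length(open) == 1L) open else
          sample(open, need[i], prob = free[open])
        memb[[i]] <- pick
        free[pick] <- free[pick] - 1L
      }
      if (ok && all(free == 0)) { membership <- memb; break }
    }
    if (is.null(membership))
      stop("infeasible: could not place nodes into modules (sizes vs on/om)")

    ## stub counts: internal per membership, remainder external
    k_int <- vector("list", N)
    for (i in seq_len(N)) {
      per <- round_half_up((1 - mu) * deg[i] / length(membership[[i]]))
      per <- pmin(per, sizes[membership[[i]]] - 1L)
      k_int[[i]] <- per
    }
    ## wire each module internally
    edges <- matrix(integer(0), 0, 2)
    for (m in seq_len(n_mod)) {
      mem <- which(vapply(membership, function(mm) m %in% mm, TRUE))
      stubs <- unlist(lapply(mem, function(i)
        rep(i, k_int[[i]][match(m, membership[[i]])])))
      edges <- rbind(edges, pair_stubs(stubs))
    }
    ## external stubs, rejecting pairs that share a module
    k_ext <- pmax(deg - vapply(k_int, sum, 0), 0)
    share <- function(a, b) mapply(function(x, y)
      length(intersect(membership[[x]], membership[[y]])) > 0, a, b)
    ext <- pair_stubs(unlist(lapply(seq_len(N), function(i) rep(i, k_ext[i]))),
                      forbidden = share)
    edges <- unique(rbind(edges, ext))

    nodes <- paste0("n", seq_len(N))
    adj <- matrix(0, N, N, dimnames = list(nodes, nodes))
    adj[edges] <- 1
    adj[edges[, 2:1, drop = FALSE]] <- 1
    net <- ppi_network(nodes, adj, weighted = FALSE)
    truth <- complex_cover(lapply(seq_len(n_mod), function(m)
      nodes[vapply(membership, function(mm) m %in% mm, TRUE)]),
      name = sprintf("lfr_truth_mu%.2f", mu))
    list(network = net, truth = truth, membership = membership)
  })
}

#' Planted-partition random network
#'
#' Small, fast fixture: `n_blocks` blocks of `block_size` nodes with
#' independent intra-block edge probability `p_in` and inter-block
#' probability `p_out`.
#'
#' @param n_blocks,block_size block count and common size.
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @return list with `network` and planted `truth` cover.
#' @export
planted_partition <- function(n_blocks, block_size, p_in, p_out, seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1)
  n <- n_blocks * block_size
  block <- rep(seq_len(n_blocks), each = block_size)
  with_seed(seed, {
    adj <- matrix(0, n, n)
    ut <- which(upper.tri(adj), arr.ind = TRUE)
    p <- ifelse(block[ut[, 1]] == block[ut[, 2]], p_in, p_out)
    e <- stats::runif(nrow(ut)) < p
    adj[ut[e, , drop = FALSE]] <- 1
    adj <- adj + t(adj)
    nodes <- paste0("n", seq_len(n))
    dimnames(adj) <- list(nodes, nodes)
    list(network = ppi_network(nodes, adj, weighted = FALSE),
         truth = complex_cover(split(nodes, block), name = "planted"))
  })
}

#' Must-link constraints from a planted ground truth
#'
#' Applies the single-membership sampling rule (see [sample_mustlinks()])
#' to a planted cover: nodes belonging to several modules contribute no
#' pairs, and a `fraction` of the pooled candidate pairs is drawn.
#'
#' @param truth planted `complex_cover`.
#' @param fraction fraction of candidate pairs to sample (`0` gives an
#'   empty set).
#' @param alpha constraint weight.
#' @param seed integer seed.
#' @return A [mustlink()] object.
#' @export
mustlinks_from_truth <- function(truth, fraction, alpha = 10, seed = 1L) {
  if (fraction == 0)
    return(mustlink(matrix(character(), 0, 2), alpha = alpha))
  sample_mustlinks(truth, fraction = fraction, alpha = alpha, seed = seed)
}
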