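#' Cluster-based permutation test against chance
#'
#' Group-level one-sample inference on decoding maps. Per point, a
#' one-sample t statistic of (accuracy - chance) across animals is
#' computed; points whose two-sided p falls below the cluster-forming
#' threshold are grouped into contiguous candidate clusters (neighbouring
#' samples in 1-D; 4-connectivity in 2-D), separately for positive and
#' negative t. Cluster mass is the sum of t within the cluster. The null
#' distribution records, for each of `n_perm` random sign-flips of the
#' per-animal difference maps, the maximal absolute cluster mass across
#' both signs jointly; each observed cluster gets
#' p = (1 + #\{null >= |mass|\}) / (1 + n_perm).
#'
#' @param maps animals x points matrix (1-D map) or animals x n1 x n2
#'   array (2-D map, e.g. train x test time).
#' @param chance chance level subtracted from the maps (0.5).
#' @param alpha significance level; also the two-sided cluster-forming
#'   threshold.
#' @param n_perm number of sign-flip permutations.
#' @param seed integer seed.
#' @return object of class `cluster_result`: list with `clusters` (each
#'   with `members` — indices into the point grid (matrix of array
#'   indices in 2-D) — `mass`, `p`, `significant`), `t_map`, `t_crit`,
#'   `alpha`, `n_perm`, `null_max_mass`, and `sig_mask` (logical map of
#'   points inside significant clusters).
#' @export
cluster_permutation <- function(maps, chance = 0.5, alpha = 0.05,
                                n_perm = 1000, seed = 1) {
  dims <- dim(maps)
  two_d <- length(dims) == 3L
  n <- dims[1]
  if (n < 2) stop("cluster permutation needs at least 2 animals")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value grid")
  grid_dim <- if (two_d) dims[2:3] else dims[2]
  X <- matrix(maps, nrow = n) - chance          # animals x points
  P <- ncol(X)
  t_obs <- clamp_t(one_sample_t(X))
  t_crit <- stats::qt(1 - alpha / 2, df = n - 1)
  obs <- find_clusters(t_obs, t_crit, grid_dim)
  null_max <- with_seed(seed, {
    out <- numeric(n_perm)
    chunk <- 100L
    done <- 0L
    q <- colSums(X^2)
    while (done < n_perm) {
      k <- min(chunk, n_perm - done)
      S <- matrix(sample(c(-1, 1), k * n, replace = TRUE), k, n)
      M <- (S %*% X) / n
      s2 <- pmax(sweep(-n * M^2, 2, q, "+"), 0) / (n - 1)
      Tm <- clamp_t(M / sqrt(s2 / n))
      for (j in seq_len(k))
        out[done + j] <- max_cluster_mass(Tm[j, ], t_crit, grid_dim)
      done <- done + k
    }
    out
  })
  clusters <- lapply(obs, function(cl) {
    p <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
    members <- if (two_d) arrayInd(cl$members, grid_dim) else cl$members
    list(members = members, mass = cl$mass, p = p,
         significant = p < alpha)
  })
  sig <- logical(P)
  for (cl in obs) {
    p <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
    if (p < alpha) sig[cl$members] <- TRUE
  }
  structure(list(clusters = clusters,
                 t_map = if (two_d) array(t_obs, grid_dim) else t_obs,
                 t_crit = t_crit, alpha = alpha, n_perm = n_perm,
                 null_max_mass = null_max,
                 sig_mask = if (two_d) array(sig, grid_dim) else sig),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  ns <- sum(vapply(x$clusters, `[[`, TRUE, "significant"))
  cat(sprintf("<cluster_result> %d candidate cluster(s), %d significant at alpha = %g (%d permutations)\n",
              length(x$clusters), ns, x$alpha, x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  mass %8.2f  p = %.4f%s\n", cl$mass, cl$p,
                if (cl$significant) "  *" else ""))
  invisible(x)
}

# Degenerate columns (zero variance across animals) yield infinite t;
# cap at a large finite value so cluster masses stay well-ordered.
clamp_t <- function(t, lim = 1e6) {
  t[is.na(t)] <- 0
  pmin(pmax(t, -lim), lim)
}

# One-sample t per column of an animals x points matrix.
one_sample_t <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt(pmax(colSums(X^2) - n * m^2, 0) / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0] <- ifelse(m[s == 0] == 0, 0, sign(m[s == 0]) * Inf)
  t
}

# Candidate clusters (both signs) of a t map. Returns a list of
# list(members = integer indices, mass = sum of t).
find_clusters <- function(tv, crit, grid_dim) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) !is.na(tv) & tv > crit else !is.na(tv) & tv < -crit
    comps <- if (length(grid_dim) == 2L)
      label_components_grid(mask, grid_dim) else label_components_runs(mask)
    for (members in comps)
      out[[length(out) + 1L]] <- list(members = members,
                                      mass = sum(tv[members]))
  }
  out
}

# Maximal absolute cluster mass of a t map (0 if no candidate cluster).
max_cluster_mass <- function(tv, crit, grid_dim) {
  tv[is.na(tv)] <- 0      # 0/0 at constant-zero columns carries no mass
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) !is.na(tv) & tv > crit else !is.na(tv) & tv < -crit
    if (!any(mask)) next
    if (length(grid_dim) == 2L) {
      comps <- label_components_grid(mask, grid_dim)
      for (members in comps) best <- max(best, abs(sum(tv[members])))
    } else {
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      cs <- cumsum(tv)
      seg <- abs(cs[ends] - c(0, cs)[starts])
      best <- max(best, seg[r$values])
    }
  }
  best
}

# Runs of TRUE in a logical vector -> list of index vectors.
label_components_runs <- function(mask) {
  if (!any(mask)) return(list())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mapply(function(s, e) s:e, starts[r$values], ends[r$values],
         SIMPLIFY = FALSE)
}

# Connected components of a logical mask on an n1 x n2 grid under
# 4-connectivity, via union-find over the masked cells.
label_components_grid <- function(mask, grid_dim) {
  cells <- which(mask)
  if (length(cells) == 0) return(list())
  n1 <- grid_dim[1]
  pos <- integer(prod(grid_dim))
  pos[cells] <- seq_along(cells)
  parent <- seq_along(cells)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rr <- ((cells - 1L) %% n1) + 1L
  for (k in seq_along(cells)) {
    cell <- cells[k]
    if (rr[k] > 1L && pos[cell - 1L] > 0L) {        # up neighbour
      a <- find(k); b <- find(pos[cell - 1L])
      if (a != b) parent[a] <- b
    }
    if (cell > n1 && pos[cell - n1] > 0L) {         # left neighbour
      a <- find(k); b <- find(pos[cell - n1])
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(seq_along(cells), find, 0L)
  split(cells, root)
}
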