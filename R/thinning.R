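# Guo-Hall homotopic thinning. Hand-written: no installed R package provides
# connectivity-preserving binary thinning. Vectorized over the whole image per
# sub-iteration; converges to an idempotent one-pixel-wide skeleton.

# shift a padded logical matrix: neighbor in direction (dr, dc) of every pixel
shift_mat <- function(p, dr, dc, nr, nc) {
  p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
}

guo_hall_pass <- function(m, phase) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  # neighbors clockwise from north: p2..p9
  p2 <- shift_mat(p, -1,  0, nr, nc); p3 <- shift_mat(p, -1,  1, nr, nc)
  p4 <- shift_mat(p,  0,  1, nr, nc); p5 <- shift_mat(p,  1,  1, nr, nc)
  p6 <- shift_mat(p,  1,  0, nr, nc); p7 <- shift_mat(p,  1, -1, nr, nc)
  p8 <- shift_mat(p,  0, -1, nr, nc); p9 <- shift_mat(p, -1, -1, nr, nc)
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) + (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  Nm <- pmin(N1, N2)
  mcond <- if (phase == 1L) ((p2 | p3 | !p5) & p4) else ((p6 | p7 | !p9) & p8)
  m & C == 1 & Nm >= 2 & Nm <= 3 & !mcond
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Guo-Hall two-subiteration homotopic thinning: connectivity-preserving and
#' idempotent (thinning a skeleton returns it unchanged). The skeleton is
#' always a subset of the input mask.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @return logical matrix of the same dimensions.
#' @export
thin_binary <- function(mask) {
  stop_if_not(is.matrix(mask), "mask must be a matrix")
  m <- mask != 0
  repeat {
    d1 <- guo_hall_pass(m, 1L); m[d1] <- FALSE
    d2 <- guo_hall_pass(m, 2L); m[d2] <- FALSE
    if (!any(d1) && !any(d2)) break
  }
  m
}

# connected components (8-connectivity) of a skeleton with per-component path
# length: 1 px per 4-neighbor step, sqrt(2) per diagonal step; a diagonal edge
# is skipped when a 4-connected detour through a common skeleton neighbor
# exists (avoids double-counting at staircase corners).
skeleton_components <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  np <- nrow(px)
  if (np == 0L)
    return(list(n = 0L,
                components = data.frame(id = integer(0), n_pixels = integer(0),
                                        length_px = numeric(0)),
                labels = matrix(0L, nrow(skel), ncol(skel))))
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(np)
  nr <- nrow(skel); nc <- ncol(skel)
  at <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- integer(length(r)); out[ok] <- id[cbind(r[ok], c[ok])]; out
  }
  r <- px[, 1]; c <- px[, 2]
  edges <- list(); wts <- list(); k <- 0L
  add_edges <- function(to, w, keep) {
    sel <- to > 0 & keep
    if (!any(sel)) return(NULL)
    list(e = cbind(seq_len(np)[sel], to[sel]), w = rep(w, sum(sel)))
  }
  # straight neighbors: right, down
  for (off in list(c(0, 1), c(1, 0))) {
    res <- add_edges(at(r + off[1], c + off[2]), 1, rep(TRUE, np))
    if (!is.null(res)) { k <- k + 1L; edges[[k]] <- res$e; wts[[k]] <- res$w }
  }
  # diagonals with 4-connected detour exclusion
  dr_dn <- at(r + 1, c + 1)
  keep <- !(at(r, c + 1) > 0 | at(r + 1, c) > 0)
  res <- add_edges(dr_dn, sqrt(2), keep)
  if (!is.null(res)) { k <- k + 1L; edges[[k]] <- res$e; wts[[k]] <- res$w }
  dl_dn <- at(r + 1, c - 1)
  keep <- !(at(r, c - 1) > 0 | at(r + 1, c) > 0)
  res <- add_edges(dl_dn, sqrt(2), keep)
  if (!is.null(res)) { k <- k + 1L; edges[[k]] <- res$e; wts[[k]] <- res$w }
  if (k > 0L) {
    e <- do.call(rbind, edges)
    w <- unlist(wts)
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, np - igraph::vcount(g)))
  } else {
    g <- igraph::make_empty_graph(n = np, directed = FALSE)
    e <- matrix(0L, 0, 2); w <- numeric(0)
  }
  comp <- igraph::components(g)
  lab <- comp$membership
  len <- numeric(comp$no)
  if (nrow(e) > 0) {
    ce <- lab[e[, 1]]
    agg <- tapply(w, ce, sum)
    len[as.integer(names(agg))] <- agg
  }
  labels <- matrix(0L, nr, nc)
  labels[px] <- lab
  list(n = comp$no,
       components = data.frame(id = seq_len(comp$no),
                               n_pixels = as.integer(tabulate(lab, comp$no)),
                               length_px = len),
       labels = labels)
}
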