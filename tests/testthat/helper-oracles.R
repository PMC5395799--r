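# Independent oracles, deliberately naive: they share no code with the
# implementation paths they check.

# All-pairs-style Bellman-Ford accumulated time on the 16-neighbour move
# graph; O(V * E), only usable on tiny grids.
bellman_ford_tt <- function(cost_values, dest, sentinel = 99999) {
  nr <- nrow(cost_values); nc <- ncol(cost_values)
  moves <- expand.grid(dr = -2:2, dc = -2:2)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  moves <- moves[pmax(abs(moves$dr), abs(moves$dc)) <= 2 &
                   !(abs(moves$dr) == 2 & abs(moves$dc) %in% c(0, 2)) &
                   !(abs(moves$dc) == 2 & abs(moves$dr) == 0), ]
  d <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(dest))) d[dest[i, 1], dest[i, 2]] <- 0
  pass <- !is.na(cost_values) & cost_values < sentinel
  for (iter in seq_len(nr * nc)) {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!pass[r, c]) next
      for (k in seq_len(nrow(moves))) {
        rr <- r + moves$dr[k]; cc <- c + moves$dc[k]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (!pass[rr, cc]) next
        w <- sqrt(moves$dr[k]^2 + moves$dc[k]^2) *
          (cost_values[r, c] + cost_values[rr, cc]) / 2
        if (d[rr, cc] + w < d[r, c]) { d[r, c] <- d[rr, cc] + w; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  d[!pass] <- sentinel
  d[is.infinite(d)] <- sentinel
  d
}

# Breadth-first drain check: TRUE iff every non-NA cell has a non-ascending
# 8-neighbour path to the grid edge.
all_cells_drain <- function(filled) {
  nr <- nrow(filled); nc <- ncol(filled)
  reach <- matrix(FALSE, nr, nc)
  edge <- row(filled) == 1 | row(filled) == nr | col(filled) == 1 |
    col(filled) == nc
  reach[edge & !is.na(filled)] <- TRUE
  repeat {
    grew <- FALSE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      # cell c can step to neighbour r (already reaching) if filled[c] >= filled[r]
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      cand <- matrix(FALSE, nr, nc)
      cand[rs - dr, cs - dc] <- reach[rs, cs] &
        (filled[rs - dr, cs - dc] >= filled[rs, cs])
      new <- cand & !reach & !is.na(filled)
      if (any(new)) { reach[new] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  all(reach[!is.na(filled)])
}

# Recursive tree-walk Strahler orders from flow directions + stream mask.
strahler_oracle <- function(flowdir, stream_mask) {
  d8 <- data.frame(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
                   dc = c(1, 1, 0, -1, -1, -1, 0, 1))
  nr <- nrow(flowdir); nc <- ncol(flowdir)
  # inflow lists
  inflows <- vector("list", nr * nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    k <- flowdir[r, c]
    if (is.na(k) || k == 0) next
    rr <- r + d8$dr[k]; cc <- c + d8$dc[k]
    if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
    i <- (cc - 1) * nr + rr
    inflows[[i]] <- c(inflows[[i]], (c - 1) * nr + r)
  }
  memo <- rep(NA_integer_, nr * nc)
  order_of <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    ups <- inflows[[i]]
    ups <- ups[stream_mask[ups]]
    o <- if (!length(ups)) 1L else {
      os <- vapply(ups, order_of, integer(1))
      m <- max(os)
      if (sum(os == m) >= 2L) m + 1L else m
    }
    memo[i] <<- o
    o
  }
  out <- matrix(0L, nr, nc)
  for (i in which(as.vector(stream_mask))) out[i] <- order_of(i)
  out
}

# Join-count statistic: number of rook-adjacent same-class pairs.
join_count <- function(m) {
  sum(m[-nrow(m), ] == m[-1, ], na.rm = TRUE) +
    sum(m[, -ncol(m)] == m[, -1], na.rm = TRUE)
}

# Straight-line Euclidean travel time on a uniform grid (seconds).
euclid_tt <- function(n, dest_rc, secs, cell_units = TRUE) {
  d <- sqrt((row(matrix(0, n, n)) - dest_rc[1])^2 +
              (col(matrix(0, n, n)) - dest_rc[2])^2)
  d * secs
}
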