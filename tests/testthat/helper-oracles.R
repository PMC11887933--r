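# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# literal 2^n enumeration of the signed-rank null distribution
enumerate_wilcoxon <- function(d, zero_policy = c("discard", "pratt"),
                               sided = c("two", "less", "greater")) {
  zero_policy <- match.arg(zero_policy)
  sided <- match.arg(sided)
  if (zero_policy == "discard") {
    dd <- d[d != 0]
    r <- rank(abs(dd))
  } else {
    r_all <- rank(abs(d))
    dd <- d[d != 0]
    r <- r_all[d != 0]
  }
  n <- length(dd)
  w_obs <- sum(r[dd > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p <- switch(sided, less = p_le, greater = p_ge,
              two = min(1, 2 * min(p_le, p_ge)))
  list(w_plus = w_obs, p = p)
}

# brute-force 4-connected component count on a logical matrix, by repeated
# label propagation (independent of the package's flood fill)
oracle_components <- function(mask) {
  lab <- matrix(seq_along(mask), nrow(mask), ncol(mask))
  lab[!mask] <- 0L
  repeat {
    new <- lab
    nr <- nrow(lab)
    up <- rbind(0L, lab[-nr, , drop = FALSE])
    dn <- rbind(lab[-1, , drop = FALSE], 0L)
    lf <- cbind(0L, lab[, -ncol(lab), drop = FALSE])
    rt <- cbind(lab[, -1, drop = FALSE], 0L)
    for (nb in list(up, dn, lf, rt)) {
      take <- mask & nb > 0L & (nb < new | new == 0L)
      new[take] <- nb[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  length(unique(lab[mask]))
}

# breadth-first connectivity oracle over explicit node/edge rules: given a
# node table (row, col, channel), connect 8-neighbours (any channel) and
# same-channel collinear pairs within the bridge/tolerance rule, then count
# components and return a membership vector
oracle_connectivity <- function(nodes, ppd, max_bridge_deg = 0.8,
                                lateral_tol_deg = 0.1) {
  n <- nrow(nodes)
  dr <- outer(nodes$row, nodes$row, `-`)
  dc <- outer(nodes$col, nodes$col, `-`)
  same_ch <- outer(nodes$channel, nodes$channel, `==`)
  linked <- pmax(abs(dr), abs(dc)) == 1  # local 8-adjacency, any channel
  axes <- list(vertical = c(1, 0), horizontal = c(0, 1),
               diag45 = c(1, 1), diag135 = c(-1, 1))
  lats <- list(vertical = c(0, 1), horizontal = c(1, 0),
               diag45 = c(1, -1), diag135 = c(1, 1))
  tol_steps <- floor(lateral_tol_deg * ppd + 1e-9)
  for (chname in names(axes)) {
    ax <- axes[[chname]]
    lt <- lats[[chname]]
    det <- ax[1] * lt[2] - ax[2] * lt[1]
    s <- (dr * lt[2] - dc * lt[1]) / det
    l <- (ax[1] * dc - ax[2] * dr) / det
    in_ch <- outer(nodes$channel == chname, nodes$channel == chname, `&`)
    ok <- in_ch & same_ch &
      abs(s - round(s)) < 1e-9 & abs(l - round(l)) < 1e-9 &
      abs(s) >= 1 & abs(s) * sqrt(sum(ax^2)) / ppd <= max_bridge_deg + 1e-9 &
      abs(l) <= tol_steps
    linked <- linked | ok
  }
  diag(linked) <- TRUE
  # label propagation to a fixpoint
  comp <- seq_len(n)
  repeat {
    new <- apply(linked, 1, function(row) min(comp[row]))
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

# build a synthetic channel map containing idealized bars: each bar is a
# 1-px-wide run of unit energy in one channel; used to probe build_graph
# against oracle_connectivity without the filtering stage
synthetic_channel_map <- function(bars, ppd = 10, half_extent_px = 60) {
  n <- 2 * half_extent_px + 1
  en <- array(0, dim = c(n, n, 4),
              dimnames = list(NULL, NULL,
                              c("vertical", "horizontal", "diag45", "diag135")))
  origin <- half_extent_px + 1
  for (b in bars) {
    ch <- match(b$channel, c("vertical", "horizontal", "diag45", "diag135"))
    step <- switch(b$channel, vertical = c(1, 0), horizontal = c(0, 1),
                   diag45 = c(1, 1), diag135 = c(-1, 1))
    for (k in 0:(b$len_px - 1)) {
      r <- origin + b$row + k * step[1]
      cc <- origin + b$col + k * step[2]
      en[r, cc, ch] <- 1
    }
  }
  structure(list(energy = en, ppd = ppd, row0 = origin, col0 = origin),
            class = "channel_map")
}

# random layout of vertical/horizontal bars for the grouping equivalence check
random_bar_layout <- function(n_bars = 6, ppd = 10) {
  bars <- list()
  for (i in seq_len(n_bars)) {
    ch <- sample(c("vertical", "horizontal"), 1)
    bars[[i]] <- list(channel = ch,
                      row = sample(-40:25, 1),
                      col = sample(-40:25, 1),
                      len_px = sample(5:15, 1))
  }
  bars
}
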