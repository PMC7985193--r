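# Independent oracles used by the tests.

# Exhaustive minimum path cost over all row sequences with |dr| <= max_step.
# Exponential; only for small grids.
brute_force_path_cost <- function(grid, max_step = 2L) {
  nr <- nrow(grid); nc <- ncol(grid)
  best <- Inf
  recurse <- function(t, r, acc) {
    acc <- acc + grid[r, t]
    if (acc >= best) return(invisible())
    if (t == nc) {
      best <<- acc
      return(invisible())
    }
    for (r2 in max(1L, r - max_step):min(nr, r + max_step))
      recurse(t + 1L, r2, acc)
  }
  for (r in seq_len(nr)) recurse(1L, r, 0)
  best
}

# closed-form chord of the half-ellipse cavity (semi-axis L along the axis,
# minor diameter D) at axial position a from the base
half_ellipse_chord <- function(a, L, D) D * sqrt(pmax(0, 1 - (a / L)^2))
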