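# shared fixtures: small grids/libraries so individual tests stay fast

small_grid <- function(n_kio = 8L, n_V = 16L, n_rho = 16L) {
  make_grid(n_kio, n_V, n_rho)
}

small_library <- function(grid = small_grid(), protocol = default_protocol()) {
  generate_library(grid, protocol, engine = "analytic", seed = 1L)
}

# brute-force weighted matcher, written independently of match_voxel:
# plain double loop with explicit tie-breaking by (residual, kio, V)
brute_force_match <- function(S, library, weights) {
  S <- S / S[1]
  best_i <- NA_integer_
  best <- c(Inf, Inf, Inf)
  for (i in seq_len(nrow(library$curves))) {
    r <- 0
    for (j in seq_along(S))
      r <- r + weights[j] * (S[j] - library$curves[i, j])^2
    key <- c(r, library$params$kio[i], library$params$V[i])
    lt <- FALSE
    for (k in 1:3) {
      if (key[k] < best[k]) { lt <- TRUE; break }
      if (key[k] > best[k]) break
    }
    if (lt) { best <- key; best_i <- i }
  }
  best_i
}

# rule-by-rule reimplementation of the nuclear counting rules (oracle)
brute_force_count <- function(table) {
  amin <- if (unique(table$region) == "tumor") 10 else 3
  n <- 0L
  for (i in seq_len(nrow(table))) {
    if (isTRUE(table$manually_added[i])) { n <- n + 1L; next }
    a <- table$xy_area_um2[i]; z <- table$z_extent_um[i]
    if (a < amin) next
    if (z < 2) next
    if (z < 7.2) n <- n + 1L else n <- n + 2L
  }
  n
}

# random nucleus-object table exercising every rule branch
random_object_table <- function(n, region, seed) {
  set.seed(seed)
  data.frame(
    object_id = seq_len(n),
    region = region,
    xy_area_um2 = stats::runif(n, 0, 40),
    z_extent_um = stats::runif(n, 0, 18)
  )
}
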