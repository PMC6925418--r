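# Brute-force enumeration oracles for the texture matrices, plus shared
# fixtures. The oracles are deliberately naive (triple loops, rle over
# explicit lines, frontier flood fill) and independent of the compiled
# engine they check.

as_qvoi <- function(lev, ng) {
  storage.mode(lev) <- "integer"
  structure(list(levels = lev, ng = as.integer(ng), algorithm = "Uniform",
                 scale_mm = 1), class = "quantized_voi")
}

oracle_glcm <- function(lev, ng, dirs = directions_13()) {
  d <- dim(lev)
  C <- matrix(0, ng, ng)
  for (k in seq_len(nrow(dirs))) {
    dd <- dirs[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      l1 <- lev[x, y, z]
      if (l1 == 0) next
      x2 <- x + dd[1]; y2 <- y + dd[2]; z2 <- z + dd[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3]) next
      l2 <- lev[x2, y2, z2]
      if (l2 == 0) next
      C[l1, l2] <- C[l1, l2] + 1
      C[l2, l1] <- C[l2, l1] + 1
    }
  }
  if (sum(C) > 0) C / sum(C) else C
}

# every line through the grid per direction, runs via rle, zeros dropped
oracle_glrlm <- function(lev, ng, dirs = directions_13()) {
  d <- dim(lev)
  runs <- list()
  inb <- function(v) all(v >= 1 & v <= d)
  for (k in seq_len(nrow(dirs))) {
    dd <- dirs[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      v <- c(x, y, z)
      if (inb(v - dd)) next  # not a line start
      seqv <- integer(0)
      while (inb(v)) {
        seqv <- c(seqv, lev[v[1], v[2], v[3]])
        v <- v + dd
      }
      r <- rle(seqv)
      keep <- r$values > 0
      if (any(keep))
        runs[[length(runs) + 1L]] <- cbind(r$values[keep], r$lengths[keep])
    }
  }
  runs <- do.call(rbind, runs)
  out <- matrix(0L, ng, max(runs[, 2]))
  for (i in seq_len(nrow(runs)))
    out[runs[i, 1], runs[i, 2]] <- out[runs[i, 1], runs[i, 2]] + 1L
  out
}

oracle_glszm <- function(lev, ng) {
  d <- dim(lev)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  seen <- array(FALSE, d)
  zones <- list()
  idx_all <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_all))) {
    v0 <- idx_all[r, ]
    if (seen[v0[1], v0[2], v0[3]]) next
    l <- lev[v0[1], v0[2], v0[3]]
    frontier <- matrix(v0, ncol = 3)
    seen[v0[1], v0[2], v0[3]] <- TRUE
    size <- 0L
    while (nrow(frontier) > 0) {
      size <- size + nrow(frontier)
      nxt <- list()
      for (i in seq_len(nrow(frontier))) {
        for (k in seq_len(nrow(offs))) {
          w <- frontier[i, ] + offs[k, ]
          if (any(w < 1) || any(w > d)) next
          if (seen[w[1], w[2], w[3]]) next
          if (lev[w[1], w[2], w[3]] != l) next
          seen[w[1], w[2], w[3]] <- TRUE
          nxt[[length(nxt) + 1L]] <- w
        }
      }
      frontier <- if (length(nxt)) do.call(rbind, nxt) else
        matrix(numeric(0), ncol = 3)
    }
    zones[[length(zones) + 1L]] <- c(l, size)
  }
  zones <- do.call(rbind, zones)
  out <- matrix(0L, ng, max(zones[, 2]))
  for (i in seq_len(nrow(zones)))
    out[zones[i, 1], zones[i, 2]] <- out[zones[i, 1], zones[i, 2]] + 1L
  out
}

oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  s <- numeric(ng)
  n <- integer(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l <- lev[x, y, z]
    if (l == 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
          z2 < 1 || z2 > d[3]) next
      l2 <- lev[x2, y2, z2]
      if (l2 > 0) nb <- c(nb, l2)
    }
    if (length(nb) > 0) {
      s[l] <- s[l] + abs(l - mean(nb))
      n[l] <- n[l] + 1L
    }
  }
  list(s = s, n = n)
}

pad_cols <- function(m, k) {
  if (ncol(m) >= k) return(m)
  cbind(m, matrix(0L, nrow(m), k - ncol(m)))
}

random_level_volume <- function(seed, max_dim = 6, max_ng = 4) {
  set.seed(seed)
  d <- c(sample(2:max_dim, 2, replace = TRUE), sample(1:3, 1))
  ng <- sample(2:max_ng, 1)
  lev <- array(sample(0:ng, prod(d), replace = TRUE,
                      prob = c(0.25, rep(0.75 / ng, ng))), d)
  lev[1:2, 1, 1] <- 1L  # guarantee at least one adjacent voxel pair
  list(lev = lev, ng = ng)
}

# shared pipeline fixtures --------------------------------------------------

accept_grid <- function() {
  extraction_grid(scales_mm = c(1, 3), algorithms = "Uniform",
                  gray_levels = c(8, 32))
}

# one full study chain on a Baseline cohort: simulate -> normalize ->
# extract -> mRMR -> 0.632+ ranking -> incremental forests -> validation AUC
pipeline_auc <- function(seed, n_per_class, intensity_effect,
                         n_bootstrap = 200) {
  spec <- cohort_spec(n_per_class = n_per_class,
                      intensity_effect = intensity_effect, seed = seed)
  cases <- generate_cohort(spec)
  tab <- cohort_feature_table(cases, accept_grid(), "Baseline")
  sel <- select_features(tab, selection_config(
    shortlist_size = 30, final_size = 8, n_bootstrap = n_bootstrap,
    seed = seed + 1))
  mod <- suppressWarnings(build_incremental_models(
    tab, sel$ranked, model_spec(max_features = 8, seed = seed + 2)))
  evaluate_model(mod, tab)$auc
}

small_cohort <- function(n_per_class = 4, seed = 1, ...) {
  generate_cohort(cohort_spec(n_per_class = n_per_class, seed = seed, ...))
}
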