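# Shared fixtures and independent brute-force oracles.

# Voxelized sphere/ellipsoid mask: centers within radius r (mm) of the grid
# center, on the given spacing.
mkSphereMask <- function(r, spacing = c(1, 1, 1), pad = 3) {
  n <- as.integer(ceiling((2 * r) / spacing) + 2 * pad + 1)
  ctr <- (n - 1) * spacing / 2
  ax <- lapply(1:3, function(i) ((seq_len(n[i]) - 1) * spacing[i] - ctr[i])^2)
  array(sqrt(outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")) <= r, n)
}

mkCubeMask <- function(dim, from, size) {
  m <- array(FALSE, dim)
  m[from[1]:(from[1] + size[1] - 1),
    from[2]:(from[2] + size[2] - 1),
    from[3]:(from[3] + size[3] - 1)] <- TRUE
  m
}

# Brute-force ANOVA mean squares by explicit sums over cells.
bruteAnova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- sum(m) / (n * k)
  ssr <- 0; ssc <- 0; sse <- 0; ssw <- 0
  rm_ <- apply(m, 1, function(x) sum(x) / k)
  cm_ <- apply(m, 2, function(x) sum(x) / n)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (m[i, j] - rm_[i] - cm_[j] + g)^2
    ssw <- ssw + (m[i, j] - rm_[i])^2
  }
  for (i in seq_len(n)) ssr <- ssr + k * (rm_[i] - g)^2
  for (j in seq_len(k)) ssc <- ssc + n * (cm_[j] - g)^2
  list(msR = ssr / (n - 1), msC = ssc / (k - 1),
       msE = sse / ((n - 1) * (k - 1)), msW = ssw / (n * (k - 1)),
       ssTotal = sum((m - g)^2))
}

# Brute-force max-max Hausdorff distance over boundary voxel centers (mm).
bruteHausdorff <- function(a, b, spacing) {
  bnd <- function(m) {
    dm <- dim(m)
    out <- array(FALSE, dm)
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
      for (k in seq_len(dm[3])) {
        if (!m[i, j, k]) next
        nb <- c(
          i == 1 || !m[i - 1, j, k], i == dm[1] || !m[i + 1, j, k],
          j == 1 || !m[i, j - 1, k], j == dm[2] || !m[i, j + 1, k],
          k == 1 || !m[i, j, k - 1], k == dm[3] || !m[i, j, k + 1])
        out[i, j, k] <- any(nb)
      }
    which(out, arr.ind = TRUE)
  }
  pa <- sweep(bnd(a) - 1, 2, spacing, "*")
  pb <- sweep(bnd(b) - 1, 2, spacing, "*")
  dmat <- as.matrix(dist(rbind(pa, pb)))[seq_len(nrow(pa)),
                                         nrow(pa) + seq_len(nrow(pb)),
                                         drop = FALSE]
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Brute-force symmetric GLCM counts by explicit pair enumeration within
# transverse slices.
bruteGlcm <- function(q, levels, dx, dy) {
  dm <- dim(q)
  counts <- matrix(0, levels, levels)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2]))
    for (i in seq_len(dm[1])) {
      a <- q[i, j, k]
      if (a == 0) next
      i2 <- i + dx; j2 <- j + dy
      if (i2 < 1 || i2 > dm[1] || j2 < 1 || j2 > dm[2]) next
      b <- q[i2, j2, k]
      if (b == 0) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  counts
}

# Rank-then-Pearson Spearman oracle.
bruteSpearman <- function(X) {
  R <- apply(X, 2, rank)
  cor(R)
}

# Tiny complete feature table for reduction/range tests.
mkFeatureTable <- function(values, patients, categories = NULL) {
  nP <- length(patients)
  tab <- data.frame(patient_id = patients,
                    arm = rep(c("manual", "semi-automatic"), length.out = nP),
                    tool_id = "T1", observer_id = "O1",
                    run = rep_len(1:2, nP), stringsAsFactors = FALSE)
  tab <- cbind(tab, values)
  if (!is.null(categories)) attr(tab, "categories") <- categories
  tab
}

# Design with all perturbation scales at zero (every contour equals truth).
zeroDesign <- function(nPatients = 3, seed = 1L) {
  zero <- observerModel()
  studyDesign(nPatients = nPatients,
              models = list("MIM-like" = zero, "Slicer-like" = zero,
                            "LSTK-like" = zero, "GrowCut-like" = zero),
              seed = seed)
}

# Shape-only mini catalog for fast structural tests.
miniCatalog <- function() {
  cat83 <- featureCatalog("default83")
  cat83[cat83$name %in% c("shp_volume", "shp_sphericity",
                          "shp_max_diameter_3d"), ]
}
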