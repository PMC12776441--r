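# Shared fixture builders and independent oracles.

suppressMessages({
  # condition-classed progress messages are noise in tests
})

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# --- tiny genomes and sites -----------------------------------------

toy_genome <- function(...) {
  genome_sequence(c(...))
}

toy_sites <- function(chrom, start, strand, motif_len,
                      score = 1, cluster = "toy") {
  binding_sites(tibble::tibble(chrom = chrom, start = start,
                               end = start + motif_len,
                               strand = strand,
                               score = rep_len(score, length(start))),
                cluster_id = cluster)
}

# --- independent oracles ---------------------------------------------

# one-sided Poisson tail by direct pmf summation
pois_tail_oracle <- function(x, lambda, upper = TRUE) {
  grid <- 0:max(x + 10, ceiling(lambda + 20 * sqrt(lambda) + 50))
  pm <- dpois(grid, lambda)
  if (upper) sum(pm[grid >= x]) else sum(pm[grid <= x])
}

# brute-force per-base interval membership
coverage_oracle <- function(intervals, chrom, n) {
  cov <- rep(FALSE, n)
  rows <- intervals[intervals$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    if (rows$end[i] >= 1) {
      lo <- max(0, rows$start[i]); hi <- min(n - 1, rows$end[i] - 1)
      if (lo <= hi) cov[(lo:hi) + 1] <- TRUE
    }
  }
  cov
}

random_intervals <- function(n, chrom = "c", size = 1000) {
  start <- sample.int(size - 10, n)
  genomic_intervals(chrom, start, start + sample.int(30, n, replace = TRUE))
}

# numeric Kabsch oracle: minimize RMSD over rotations via optim
kabsch_rmsd_oracle <- function(S, O) {
  O <- sweep(O, 2, colMeans(O))
  S <- sweep(S, 2, colMeans(S))
  rotmat <- function(v) uvfootprint:::.rot_exp(v)
  f <- function(v) sqrt(mean(rowSums((S %*% t(rotmat(v)) - O)^2)))
  best <- Inf
  for (init in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                    c(0, 0, pi / 2), c(1, 1, 1), c(-1, 2, 0.5))) {
    r <- optim(init, f, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# dihedral oracle (independent of the package's implementation)
dihedral_oracle <- function(p1, p2, p3, p4) {
  u <- p2 - p1; v <- p3 - p2; w <- p4 - p3
  n1 <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  n2 <- c(v[2] * w[3] - v[3] * w[2], v[3] * w[1] - v[1] * w[3],
          v[1] * w[2] - v[2] * w[1])
  x <- sum(n1 * n2)
  y <- sum(c(n1[2] * n2[3] - n1[3] * n2[2],
             n1[3] * n2[1] - n1[1] * n2[3],
             n1[1] * n2[2] - n1[2] * n2[1]) * v) / sqrt(sum(v^2))
  atan2(y, x) * 180 / pi
}

# --- structure fixtures ----------------------------------------------

# frame composition used as the independent construction oracle for
# step-parameter round trips
compose_frame <- function(f, translation, rotation_deg) {
  v <- rotation_deg * pi / 180
  Rrel <- uvfootprint:::.rot_exp(v)
  Rh <- uvfootprint:::.rot_exp(v / 2)
  Rm <- f$axes %*% Rh
  list(origin = f$origin + as.numeric(Rm %*% translation),
       axes = f$axes %*% Rrel)
}

identity_frame <- function() list(origin = c(0, 0, 0), axes = diag(3))

# place a residue's ring (+ optional sugar) atoms given a base frame
ring_atoms_at <- function(base, frame, chain, resno, b = 90,
                          sugar_phase = NULL, sugar_amp = 0.45) {
  std <- uvfootprint:::.standard_base(base)
  local_atoms <- std$atoms
  if (base %in% c("T", "C", "U")) {
    # exocyclic acceptor on C4 (O4 for T/U, N4 for C), in the base plane
    c4 <- local_atoms["C4", ]
    outward <- c4 / sqrt(sum(c4^2))
    acc <- rbind(c4 + 1.23 * outward)
    rownames(acc) <- if (base == "C") "N4" else "O4"
    local_atoms <- rbind(local_atoms, acc)
  }
  xyz <- local_atoms %*% t(frame$axes)
  xyz <- sweep(xyz, 2, frame$origin, "+")
  resname <- paste0("D", base)
  out <- tibble::tibble(chain = chain, resno = resno, resname = resname,
                        atom = rownames(local_atoms),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = b)
  if (!is.null(sugar_phase)) {
    ring <- t(vapply(0:4, function(j) {
      a <- 2 * pi * j / 5
      c(1.2 * cos(a) + 4.5, 1.2 * sin(a),
        sugar_amp * cos(sugar_phase * pi / 180 + 4 * pi * j / 5))
    }, numeric(3)))
    ring <- ring %*% t(frame$axes)
    ring <- sweep(ring, 2, frame$origin, "+")
    out <- dplyr::bind_rows(out, tibble::tibble(
      chain = chain, resno = resno, resname = resname,
      atom = c("C1'", "C2'", "C3'", "C4'", "O4'"),
      x = ring[, 1], y = ring[, 2], z = ring[, 3], b = b))
  }
  out
}

# synthetic B-DNA-like duplex: sequence on chain A, complement on chain B,
# uniform twist/rise steps; returns a uvf_structure
synthetic_duplex <- function(seq, twist = 36, rise = 3.4, b = 90,
                             sugar_phase = 160) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nchar(seq)
  atoms <- list()
  pair <- identity_frame()
  for (i in seq_len(n)) {
    base <- substr(seq, i, i)
    f2 <- pair
    f2$axes <- pair$axes %*% diag(c(1, -1, -1))
    atoms[[length(atoms) + 1L]] <-
      ring_atoms_at(base, pair, "A", i, b = b, sugar_phase = sugar_phase)
    atoms[[length(atoms) + 1L]] <-
      ring_atoms_at(comp[[base]], f2, "B", n + 1 - i, b = b,
                    sugar_phase = sugar_phase)
    pair <- compose_frame(pair, c(0, 0, rise), c(0, 0, twist))
  }
  structure_model(dplyr::bind_rows(atoms))
}

# apply a rigid motion to every atom of a structure
rigid_move <- function(model, rotation_deg = c(25, -40, 60),
                       translation = c(5, -3, 12)) {
  R <- uvfootprint:::.rot_exp(rotation_deg * pi / 180)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, translation, "+")
  out <- model
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}
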