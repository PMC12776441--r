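# Photoreactivity geometry of dipyrimidine steps from structure
# coordinate files: distance proxies for the two UV photoproducts
# (d22 for cyclobutane dimers, d64 for 6-4 photoproducts), base stacking
# overlap, base-pair/base-step parameters via a symmetric mid-frame
# scheme, and sugar pseudorotation.

DNA_RESNAMES <- c(DA = "A", DC = "C", DG = "G", DT = "T",
                  A = "A", C = "C", G = "G", T = "T",
                  DU = "U", U = "U")

PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")
PURINE_RING <- c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")
SUGAR_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "O4'")

PUCKER_LABELS <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo",
                   "C2'-endo", "C3'-exo", "C4'-endo", "O4'-exo",
                   "C1'-endo", "C2'-exo")

#' Structure model from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `x`, `y`, `z`, `b` (per-atom confidence, e.g. pLDDT, in the
#'   temperature-factor field).
#' @return Tibble of class `uvf_structure`, ordered by chain and residue
#'   number (taken as 5'->3' order within DNA chains).
#' @export
structure_model <- function(atoms) {
  cols <- c("chain", "resno", "resname", "atom", "x", "y", "z", "b")
  if (!all(cols %in% names(atoms))) {
    stop("atom table needs columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  a <- tibble::as_tibble(atoms)[, cols]
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  a$atom <- gsub("\\*", "'", a$atom)  # old-style primes
  a$base <- unname(DNA_RESNAMES[a$resname])
  dup <- duplicated(a[, c("chain", "resno", "atom")])
  if (any(dup)) stop("duplicate atom names within a residue",
                     call. = FALSE)
  a <- dplyr::arrange(a, .data$chain, .data$resno)
  if (!any(!is.na(a$base))) stop("no DNA chain found", call. = FALSE)
  structure(a, class = c("uvf_structure", class(tibble::tibble())))
}

#' Load a structure from PDB or mmCIF
#'
#' PDB parsing is delegated to [bio3d::read.pdb()]; mmCIF files are read
#' with a minimal `_atom_site` loop parser sufficient for predicted-model
#' output.  Per-atom confidence is taken from the temperature-factor
#' field.
#'
#' @param path File path ending in `.pdb` or `.cif`.
#' @return A `uvf_structure`.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    atoms <- .read_cif_atoms(path)
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    atoms <- tibble::tibble(chain = pdb$atom$chain,
                            resno = pdb$atom$resno,
                            resname = trimws(pdb$atom$resid),
                            atom = trimws(pdb$atom$elety),
                            x = pdb$atom$x, y = pdb$atom$y,
                            z = pdb$atom$z, b = pdb$atom$b)
  }
  structure_model(atoms)
}

# minimal mmCIF _atom_site reader
.read_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0L) stop("no _atom_site loop in ", path,
                                  call. = FALSE)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body <- lines[(max(hdr_idx) + 1):length(lines)]
  stop_at <- which(grepl("^(#|loop_|_[A-Za-z])", body))[1]
  if (!is.na(stop_at)) body <- body[seq_len(stop_at - 1)]
  body <- body[grepl("^(ATOM|HETATM)", body)]
  toks <- strsplit(trimws(body), "\\s+")
  m <- do.call(rbind, toks)
  if (ncol(m) != length(fields)) {
    stop("malformed _atom_site loop in ", path, call. = FALSE)
  }
  colnames(m) <- fields
  pick <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  unquote <- function(x) gsub("^\"|\"$", "", x)
  tibble::tibble(
    chain = pick("auth_asym_id", "label_asym_id"),
    resno = as.integer(pick("auth_seq_id", "label_seq_id")),
    resname = pick("label_comp_id", "auth_comp_id"),
    atom = unquote(pick("label_atom_id", "auth_atom_id")),
    x = as.numeric(pick("Cartn_x")), y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    b = as.numeric(pick("B_iso_or_equiv")))
}

#' DNA residue summary of a structure
#'
#' @param model A `uvf_structure`.
#' @return Tibble `chain`, `resno`, `base`, `mean_confidence` (mean of
#'   the temperature-factor field over all atoms of the residue),
#'   ordered 5'->3' within each chain.
#' @export
dna_residues <- function(model) {
  model |>
    dplyr::filter(!is.na(.data$base)) |>
    dplyr::group_by(.data$chain, .data$resno, .data$base) |>
    dplyr::summarise(mean_confidence = mean(.data$b), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno)
}

#' Confidence filter with terminal trimming
#'
#' Removes `trim_bp` residues from either end of every DNA chain (model
#' termini are systematically low-confidence), then fails the structure
#' if any retained DNA residue's mean confidence is below
#' `min_mean_plddt`.
#'
#' @param model A `uvf_structure`.
#' @param min_mean_plddt Per-residue mean confidence threshold.
#' @param trim_bp Residues trimmed from each chain end.
#' @return List `pass` (logical), `residues` (retained residue tibble),
#'   `failing` (residues below threshold after trimming).
#' @export
confidence_filter <- function(model, min_mean_plddt = 70, trim_bp = 3L) {
  res <- dna_residues(model)
  kept <- res |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(.i = dplyr::row_number(), .n = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.i > trim_bp, .data$.i <= .data$.n - trim_bp)
  kept$.i <- NULL; kept$.n <- NULL
  failing <- kept[kept$mean_confidence < min_mean_plddt, , drop = FALSE]
  list(pass = nrow(failing) == 0L, residues = kept, failing = failing)
}

# ---- elementary vector geometry -------------------------------------

.atom_xyz <- function(model, chain, resno, atom) {
  row <- model[model$chain == chain & model$resno == resno &
                 model$atom == atom, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("atom ", atom, " missing in ", chain, ":", resno, call. = FALSE)
  }
  c(row$x, row$y, row$z)
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  y <- sum(.cross(n1, n2) * b2 / sqrt(sum(b2^2)))
  atan2(y, sum(n1 * n2)) * 180 / pi
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Photoproduct distance proxies for a dipyrimidine step
#'
#' `d22()` is the distance between the C5-C6 bond midpoints of two
#' adjacent pyrimidines (the two carbons that form the cyclobutane ring
#' of a CPD).  `d64()` is the distance between the 5' pyrimidine's C5 and
#' the exocyclic acceptor attached to the 3' pyrimidine's C4 — O4 for
#' thymine, N4 for cytosine — the atoms linked in a 6-4 photoproduct.
#'
#' @param model A `uvf_structure`.
#' @param res5,res3 Lists `list(chain =, resno =)` identifying the 5' and
#'   3' residues.
#' @return Distance in Angstroms.
#' @export
d22 <- function(model, res5, res3) {
  mid <- function(res) {
    (.atom_xyz(model, res$chain, res$resno, "C5") +
       .atom_xyz(model, res$chain, res$resno, "C6")) / 2
  }
  .check_pyrimidine(model, res5); .check_pyrimidine(model, res3)
  sqrt(sum((mid(res5) - mid(res3))^2))
}

#' @rdname d22
#' @export
d64 <- function(model, res5, res3) {
  .check_pyrimidine(model, res5); .check_pyrimidine(model, res3)
  base3 <- .residue_base(model, res3)
  acceptor <- if (base3 == "T") "O4" else "N4"
  a <- .atom_xyz(model, res5$chain, res5$resno, "C5")
  b <- .atom_xyz(model, res3$chain, res3$resno, acceptor)
  sqrt(sum((a - b)^2))
}

.residue_base <- function(model, res) {
  b <- unique(model$base[model$chain == res$chain &
                           model$resno == res$resno])
  b <- b[!is.na(b)]
  if (length(b) != 1L) stop("residue ", res$chain, ":", res$resno,
                            " is not a DNA base", call. = FALSE)
  b
}

.check_pyrimidine <- function(model, res) {
  if (!.residue_base(model, res) %in% c("C", "T", "U")) {
    stop("residue ", res$chain, ":", res$resno, " is not a pyrimidine",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Report DNA residues with missing ring atoms
#'
#' @param model A `uvf_structure`.
#' @return Tibble `chain`, `resno`, `base`, `missing` (comma-separated
#'   missing ring atom names); empty when complete.
#' @export
missing_ring_atoms <- function(model) {
  res <- dna_residues(model)
  out <- list()
  for (i in seq_len(nrow(res))) {
    need <- if (res$base[i] %in% c("A", "G")) PURINE_RING
            else PYRIMIDINE_RING
    have <- model$atom[model$chain == res$chain[i] &
                         model$resno == res$resno[i]]
    miss <- setdiff(need, have)
    if (length(miss)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chain = res$chain[i], resno = res$resno[i], base = res$base[i],
        missing = paste(miss, collapse = ","))
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chain = character(0), resno = integer(0),
                          base = character(0), missing = character(0)))
  }
  dplyr::bind_rows(out)
}

# ---- standard bases and reference frames ----------------------------

# Idealized planar ring geometries used as fitting references: regular
# polygons with aromatic-ring bond lengths (1.39 A six-ring edge), built
# once in the base plane z = 0 with the frame origin at the ring centroid
# and the x-axis through the glycosidic nitrogen.  Exact agreement with
# any particular external standard is not required: all reported
# parameters are differences between frames fitted with the same
# reference, and the construction/recovery round-trip is exact.
.standard_base <- local({
  hexagon <- function(names, bond = 1.39) {
    r <- bond / (2 * sin(pi / 6))
    ang <- pi / 2 - (seq_along(names) - 1) * pi / 3
    m <- cbind(r * cos(ang), r * sin(ang), 0)
    rownames(m) <- names
    m <- sweep(m, 2, colMeans(m))
    # x-axis through the first (glycosidic) atom
    x1 <- m[1, ] / sqrt(sum(m[1, ]^2))
    z1 <- c(0, 0, 1)
    y1 <- .cross(z1, x1)
    R <- rbind(x1, y1, z1)
    m %*% t(R)
  }
  pyr <- hexagon(PYRIMIDINE_RING)
  # purine: pyrimidine six-ring fused with a five-ring at C4-C5
  six <- hexagon(c("N1", "C2", "N3", "C4", "C5", "C6"))
  c4 <- six["C4", ]; c5 <- six["C5", ]
  mid45 <- (c4 + c5) / 2
  out_dir <- mid45 / sqrt(sum(mid45^2))
  edge <- sqrt(sum((c5 - c4)^2))
  # regular pentagon on the shared edge
  apo <- edge / (2 * tan(pi / 5))  # apothem
  rad <- edge / (2 * sin(pi / 5))
  cen <- mid45 + out_dir * apo
  axis_ang <- atan2(c5[2] - cen[2], c5[1] - cen[1])
  five <- t(vapply(0:4, function(k) {
    a <- axis_ang + k * 2 * pi / 5
    c(cen[1] + rad * cos(a), cen[2] + rad * sin(a), 0)
  }, numeric(3)))
  rownames(five) <- c("C5", "N7", "C8", "N9", "C4")
  pur <- rbind(six, five[c("N7", "C8", "N9"), ])
  pur <- pur[PURINE_RING, ]
  pur <- sweep(pur, 2, colMeans(pur))
  x1 <- pur["N9", ] / sqrt(sum(pur["N9", ]^2))
  y1 <- .cross(c(0, 0, 1), x1)
  pur <- pur %*% t(rbind(x1, y1, c(0, 0, 1)))
  function(base) {
    if (base %in% c("A", "G")) list(atoms = pur, ring = PURINE_RING)
    else list(atoms = pyr, ring = PYRIMIDINE_RING)
  }
})

#' Fit a reference frame to a base by rigid superposition
#'
#' Least-squares (Kabsch) superposition of the packaged standard ring
#' geometry onto the observed ring atoms, with the reflection excluded;
#' the fitted frame is the image of the standard frame (origin at the
#' ring centroid, z normal to the base plane, x through the glycosidic
#' nitrogen).
#'
#' @param model A `uvf_structure`.
#' @param chain,resno Residue identifier.
#' @return List `origin` (length-3), `axes` (3x3 matrix, columns x, y,
#'   z), `rmsd`, `base`.
#' @export
fit_base_frame <- function(model, chain, resno) {
  res <- list(chain = chain, resno = resno)
  base <- .residue_base(model, res)
  std <- .standard_base(base)
  obs <- t(vapply(std$ring, function(a) .atom_xyz(model, chain, resno, a),
                  numeric(3)))
  cen_obs <- colMeans(obs)
  O <- sweep(obs, 2, cen_obs)
  S <- std$atoms
  if (qr(O)$rank < 2) stop("degenerate (collinear) ring atoms",
                           call. = FALSE)
  H <- t(S) %*% O
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)  # maps standard -> observed
  fitted <- S %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - O)^2)))
  list(origin = cen_obs, axes = R, rmsd = rmsd, base = base)
}

# rotation exp/log maps
.rot_exp <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.rot_log <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  ax * th
}

# symmetric mid-frame decomposition between two frames
.mid_frame_params <- function(f1, f2) {
  R_rel <- t(f1$axes) %*% f2$axes
  v <- .rot_log(R_rel)          # axis*angle, frame-1 coordinates
  Rm <- f1$axes %*% .rot_exp(v / 2)
  tr <- as.numeric(t(Rm) %*% (f2$origin - f1$origin))
  rot <- v * 180 / pi           # components about mid-frame axes
  list(translation = tr, rotation = rot, mid = list(origin =
    (f1$origin + f2$origin) / 2, axes = Rm))
}

#' Base-pair and base-step parameters via the symmetric mid-frame scheme
#'
#' `base_pair_params()` flips the second (complementary) base's frame
#' about its x-axis (anti-parallel convention) and decomposes the
#' relative placement in the pair mid-frame: translations are shear,
#' stretch, stagger; rotations about the mid-frame x, y, z axes are
#' buckle, propeller, opening.  `base_step_params()` decomposes two
#' successive (pair or base) frames the same way into shift, slide, rise
#' and tilt, roll, twist.  Frame pairs misoriented beyond the
#' anti-parallel tolerance are flagged.
#'
#' @param frame1,frame2 Frames from [fit_base_frame()] (or a pair
#'   mid-frame from `base_pair_params()$pair_frame`).
#' @return Named list of the six parameters (degrees / Angstroms), plus
#'   `pair_frame` / `mid_frame` and `flagged`.
#' @export
base_pair_params <- function(frame1, frame2) {
  flip <- frame2
  flip$axes <- frame2$axes %*% diag(c(1, -1, -1))
  flagged <- sum(frame1$axes[, 3] * flip$axes[, 3]) < 0
  mp <- .mid_frame_params(frame1, flip)
  list(shear = mp$translation[1], stretch = mp$translation[2],
       stagger = mp$translation[3], buckle = mp$rotation[1],
       propeller = mp$rotation[2], opening = mp$rotation[3],
       pair_frame = mp$mid, flagged = flagged)
}

#' @rdname base_pair_params
#' @export
base_step_params <- function(frame1, frame2) {
  mp <- .mid_frame_params(frame1, frame2)
  list(shift = mp$translation[1], slide = mp$translation[2],
       rise = mp$translation[3], tilt = mp$rotation[1],
       roll = mp$rotation[2], twist = mp$rotation[3],
       mid_frame = mp$mid, flagged = FALSE)
}

#' @rdname base_pair_params
#' @param frames1,frames2 Lists of base frames: strand-I bases 5'->3' and
#'   their complementary partners (same order).
#' @return For `pair_and_step_params()`: list of tibbles `pairs` and
#'   `steps`.
#' @export
pair_and_step_params <- function(frames1, frames2) {
  stopifnot(length(frames1) == length(frames2), length(frames1) >= 1)
  pairs <- list(); pair_frames <- list()
  for (i in seq_along(frames1)) {
    pp <- base_pair_params(frames1[[i]], frames2[[i]])
    pair_frames[[i]] <- pp$pair_frame
    pairs[[i]] <- tibble::tibble(pair = i, shear = pp$shear,
                                 stretch = pp$stretch,
                                 stagger = pp$stagger,
                                 buckle = pp$buckle,
                                 propeller = pp$propeller,
                                 opening = pp$opening,
                                 flagged = pp$flagged)
  }
  steps <- list()
  if (length(pair_frames) >= 2) {
    for (i in seq_len(length(pair_frames) - 1)) {
      sp <- base_step_params(pair_frames[[i]], pair_frames[[i + 1]])
      steps[[i]] <- tibble::tibble(step = i, shift = sp$shift,
                                   slide = sp$slide, rise = sp$rise,
                                   tilt = sp$tilt, roll = sp$roll,
                                   twist = sp$twist)
    }
  }
  list(pairs = dplyr::bind_rows(pairs), steps = dplyr::bind_rows(steps))
}

#' Interbase angle from propeller and buckle
#'
#' The root of summed squares, `sqrt(propeller^2 + buckle^2)`.
#'
#' @param propeller,buckle Angles in degrees.
#' @return Angle in degrees.
#' @export
interbase_angle <- function(propeller, buckle) {
  sqrt(propeller^2 + buckle^2)
}

# ---- stacking overlap ------------------------------------------------

# area of a simple polygon (shoelace; vertices in order)
.poly_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# Sutherland-Hodgman clip of polygon p (counter-clockwise) by convex
# clip polygon q (counter-clockwise)
.clip_convex <- function(p, q) {
  ensure_ccw <- function(m) {
    n <- nrow(m); i2 <- c(2:n, 1)
    if (sum(m[, 1] * m[i2, 2] - m[i2, 1] * m[, 2]) < 0) m[n:1, ] else m
  }
  p <- ensure_ccw(p); q <- ensure_ccw(q)
  out <- p
  nq <- nrow(q)
  for (e in seq_len(nq)) {
    if (nrow(out) == 0L) return(out)
    a <- q[e, ]; b <- q[if (e == nq) 1 else e + 1, ]
    inside <- function(pt) {
      (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1]) >=
        -1e-12
    }
    inter <- function(p1, p2) {
      d1 <- p2 - p1; d2 <- b - a
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((a[1] - p1[1]) * d2[2] - (a[2] - p1[2]) * d2[1]) / den
      p1 + t * d1
    }
    np <- nrow(out)
    res <- list()
    for (i in seq_len(np)) {
      cur <- out[i, ]; nxt <- out[if (i == np) 1 else i + 1, ]
      ci <- inside(cur); ni <- inside(nxt)
      if (ci) res[[length(res) + 1L]] <- cur
      if (xor(ci, ni)) res[[length(res) + 1L]] <- inter(cur, nxt)
    }
    out <- if (length(res)) do.call(rbind, res) else
      matrix(numeric(0), 0, 2)
  }
  out
}

#' Intersection area of two convex polygons
#'
#' @param poly1,poly2 n x 2 vertex matrices (any vertex order).
#' @return Overlap area.
#' @export
convex_overlap_area <- function(poly1, poly2) {
  clipped <- .clip_convex(poly1, poly2)
  if (nrow(clipped) < 3L) return(0)
  .poly_area(clipped)
}

#' Stacking overlap of two base rings
#'
#' Projects both rings (ring atoms only, exocyclic atoms excluded) into
#' the mean base plane — normal given by the normalized sum of the two
#' base-plane unit normals, anchored at the midpoint of the ring
#' centroids — and returns the area of the convex polygon intersection.
#' Near-perpendicular bases (normal sum close to zero) are flagged and
#' return `NA`.
#'
#' @param model A `uvf_structure`.
#' @param res5,res3 Residue identifiers as in [d22()].
#' @return Overlap area in square Angstroms (`NA` if flagged).
#' @export
stacking_overlap <- function(model, res5, res3) {
  ring_coords <- function(res) {
    base <- .residue_base(model, res)
    ring <- if (base %in% c("A", "G")) PURINE_RING else PYRIMIDINE_RING
    # project the six- (or nine-) ring in its canonical order
    t(vapply(ring, function(a) .atom_xyz(model, res$chain, res$resno, a),
             numeric(3)))
  }
  r1 <- ring_coords(res5); r2 <- ring_coords(res3)
  normal_of <- function(m) {
    c0 <- sweep(m, 2, colMeans(m))
    sv <- svd(c0)
    sv$v[, 3]
  }
  n1 <- normal_of(r1); n2 <- normal_of(r2)
  if (sum(n1 * n2) < 0) n2 <- -n2
  ns <- n1 + n2
  if (sqrt(sum(ns^2)) < 1e-6) {
    uvf_inform("stacking_overlap: near-perpendicular bases; no value")
    return(NA_real_)
  }
  n <- ns / sqrt(sum(ns^2))
  anchor <- (colMeans(r1) + colMeans(r2)) / 2
  # in-plane basis
  u <- .cross(n, if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  u <- u / sqrt(sum(u^2))
  v <- .cross(n, u)
  project <- function(m) {
    d <- sweep(m, 2, anchor)
    cbind(d %*% u, d %*% v)
  }
  convex_overlap_area(project(r1), project(r2))
}

# ---- sugar pucker ----------------------------------------------------

#' Sugar ring pseudorotation phase and pucker
#'
#' Computes the five endocyclic torsions nu0..nu4 from the sugar atoms
#' C1'-C4', O4' and the pseudorotation phase
#' `tan(P) = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' with the quadrant fixed by the sign of nu2; amplitude is
#' `nu2 / cos(P)`; the pucker label is the 36-degree window containing P
#' (C3'-endo at P = 0).
#'
#' @param model A `uvf_structure`.
#' @param chain,resno Residue identifier.
#' @return List `nu` (numeric(5)), `phase` (deg, in \[0, 360)),
#'   `amplitude` (deg), `pucker` (label), `flagged` (logical; `TRUE`
#'   when |nu2| is too small for a stable quadrant).
#' @export
pseudorotation <- function(model, chain, resno) {
  at <- function(a) .atom_xyz(model, chain, resno, a)
  c1 <- at("C1'"); c2 <- at("C2'"); c3 <- at("C3'"); c4 <- at("C4'")
  o4 <- at("O4'")
  nu <- c(.dihedral(c4, o4, c1, c2),
          .dihedral(o4, c1, c2, c3),
          .dihedral(c1, c2, c3, c4),
          .dihedral(c2, c3, c4, o4),
          .dihedral(c3, c4, o4, c1))
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  flagged <- abs(nu[3]) < 1e-6
  if (flagged) {
    # quadrant from the numerator alone when nu2 vanishes (P near 90/270)
    P <- if (num >= 0) 90 else 270
    amp <- abs(num) / (2 * (sin(36 * pi / 180) + sin(72 * pi / 180)))
  } else {
    P <- atan(num / den) * 180 / pi
    if (nu[3] < 0) P <- P + 180
    P <- P %% 360
    amp <- nu[3] / cos(P * pi / 180)
  }
  list(nu = nu, phase = P, amplitude = amp,
       pucker = PUCKER_LABELS[floor(P / 36) + 1L], flagged = flagged)
}

# ---- state comparison ------------------------------------------------

#' Compare geometric parameter ensembles between binding states
#'
#' Per-parameter medians, fold change of medians (bound / unbound) and a
#' two-sided Mann-Whitney U test between the TF-bound and unbound
#' ensembles, with optional flags where the bound median falls inside a
#' configured reactive range.
#'
#' @param bound,unbound Data frames of per-step geometry (numeric
#'   parameter columns; identical column sets compared).
#' @param thresholds Optional named list `parameter = c(lo, hi)` of
#'   reactive ranges; no defaults are supplied.
#' @param min_n Minimum observations per state per parameter.
#' @return Tibble `parameter`, `n_bound`, `n_unbound`, `median_bound`,
#'   `median_unbound`, `fold_change`, `p`, `in_reactive_range`.
#' @export
compare_states <- function(bound, unbound, thresholds = NULL,
                           min_n = 3L) {
  params <- intersect(names(bound)[vapply(bound, is.numeric, logical(1))],
                      names(unbound)[vapply(unbound, is.numeric,
                                            logical(1))])
  out <- list()
  for (pm in params) {
    xb <- bound[[pm]][is.finite(bound[[pm]])]
    xu <- unbound[[pm]][is.finite(unbound[[pm]])]
    if (length(xb) < min_n || length(xu) < min_n) {
      uvf_inform(paste0("compare_states: ", pm,
                        " has too few observations; excluded"))
      next
    }
    p <- if (identical(sort(xb), sort(xu))) 1 else
      suppressWarnings(stats::wilcox.test(xb, xu,
                                          exact = FALSE))$p.value
    mb <- stats::median(xb); mu <- stats::median(xu)
    flag <- NA
    if (!is.null(thresholds) && pm %in% names(thresholds)) {
      rng <- sort(thresholds[[pm]])
      flag <- mb >= rng[1] & mb <= rng[2]
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      parameter = pm, n_bound = length(xb), n_unbound = length(xu),
      median_bound = mb, median_unbound = mu,
      fold_change = mb / mu, p = p, in_reactive_range = flag)
  }
  dplyr::bind_rows(out)
}

#' Photoreactivity geometry ensemble for every dipyrimidine step
#'
#' Scans a DNA chain 5'->3' and, for every adjacent pyrimidine pair,
#' computes the photoproduct distance proxies, stacking overlap,
#' base-step shift/slide (between the two base frames, or between pair
#' frames when the complementary chain is supplied), sugar pseudorotation
#' of both residues, and — when the partner chain is given (partner of
#' residue i is the reversed-order residue of the complementary chain) —
#' propeller, buckle (averaged over the step's two base pairs) and the
#' interbase angle.
#'
#' @param model A `uvf_structure`.
#' @param chain DNA chain to scan.
#' @param partner_chain Optional complementary chain (anti-parallel,
#'   same length).
#' @param state Label stored in the output (`"bound"` / `"unbound"`).
#' @param residues Optional residue tibble (e.g.
#'   [confidence_filter()]`$residues`) restricting the scan.
#' @return Tibble with one row per dipyrimidine step.
#' @export
dipyrimidine_geometry <- function(model, chain, partner_chain = NULL,
                                  state = "bound", residues = NULL) {
  res <- dna_residues(model)
  res <- res[res$chain == chain, , drop = FALSE]
  if (!is.null(residues)) {
    res <- res[paste(res$chain, res$resno) %in%
                 paste(residues$chain, residues$resno), , drop = FALSE]
  }
  partner <- NULL
  if (!is.null(partner_chain)) {
    partner <- dna_residues(model)
    partner <- partner[partner$chain == partner_chain, , drop = FALSE]
    partner <- partner[rev(seq_len(nrow(partner))), , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(res) - 1L)) {
    if (!res$base[i] %in% c("C", "T") || !res$base[i + 1] %in% c("C", "T"))
      next
    r5 <- list(chain = chain, resno = res$resno[i])
    r3 <- list(chain = chain, resno = res$resno[i + 1])
    f5 <- fit_base_frame(model, chain, res$resno[i])
    f3 <- fit_base_frame(model, chain, res$resno[i + 1])
    propeller <- buckle <- NA_real_
    if (!is.null(partner) && nrow(partner) == nrow(res)) {
      pp <- lapply(c(i, i + 1L), function(j) {
        fp <- fit_base_frame(model, partner_chain, partner$resno[j])
        base_pair_params(fit_base_frame(model, chain, res$resno[j]), fp)
      })
      propeller <- mean(vapply(pp, `[[`, numeric(1), "propeller"))
      buckle <- mean(vapply(pp, `[[`, numeric(1), "buckle"))
      sp <- base_step_params(pp[[1]]$pair_frame, pp[[2]]$pair_frame)
    } else {
      sp <- base_step_params(f5, f3)
    }
    pk5 <- pseudorotation(model, chain, res$resno[i])
    pk3 <- pseudorotation(model, chain, res$resno[i + 1])
    out[[length(out) + 1L]] <- tibble::tibble(
      state = state, chain = chain, resno5 = res$resno[i],
      dinuc = paste0(res$base[i], res$base[i + 1]),
      d22 = d22(model, r5, r3), d64 = d64(model, r5, r3),
      stacking_overlap = stacking_overlap(model, r5, r3),
      shift = sp$shift, slide = sp$slide,
      propeller = propeller, buckle = buckle,
      interbase_angle = interbase_angle(propeller, buckle),
      phase5 = pk5$phase, pucker5 = pk5$pucker,
      phase3 = pk3$phase, pucker3 = pk3$pucker)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(state = character(0), chain = character(0),
                          resno5 = integer(0), dinuc = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Select representative binding-site sequences for structure prediction
#'
#' The top `n` non-redundant (unique-sequence) sites by motif score, each
#' as a fixed-length sequence centered at the motif center — the input
#' recipe for predicted TF-DNA complex generation.
#'
#' @param sites A `uvf_sites` table.
#' @param genome A `uvf_genome`.
#' @param n Number of sequences.
#' @param length Sequence length (bp).
#' @return Tibble `chrom`, `start`, `end`, `strand`, `score`,
#'   `sequence` (motif-strand orientation).
#' @export
select_structure_sites <- function(sites, genome, n = 20L, length = 20L) {
  centers <- site_center(sites)
  half <- floor(length / 2)
  # orient the window so the motif center lands at the same offset of
  # the motif-strand sequence for sites on either strand
  start <- ifelse(sites$strand == "+", centers - half,
                  centers + half + 1 - length)
  end <- start + length
  seqs <- substring(unclass(genome)[sites$chrom], start + 1, end)
  mi <- sites$strand == "-"
  seqs[mi] <- revcomp(seqs[mi])
  d <- tibble::tibble(chrom = sites$chrom, start = start, end = end,
                      strand = sites$strand, score = sites$score,
                      sequence = seqs)
  d <- d[order(-d$score, d$chrom, d$start), , drop = FALSE]
  d <- d[!duplicated(d$sequence), , drop = FALSE]
  utils::head(d, n)
}
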