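#' Minimal structure container
#'
#' Structures are plain data frames with columns `atom` (atom name),
#' `resid` (residue name), `resno` (residue number), `chain`, and Cartesian
#' `x`, `y`, `z` in Angstrom, carrying class `"structure_df"`.
#'
#' @param atom,resid,resno,chain Per-atom annotation vectors.
#' @param xyz Numeric n x 3 coordinate matrix.
#' @return A `"structure_df"` data frame.
#' @export
structure_df <- function(atom, resid, resno, chain, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(atom))
  out <- data.frame(atom = as.character(atom), resid = as.character(resid),
                    resno = as.integer(resno), chain = as.character(chain),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  class(out) <- c("structure_df", "data.frame")
  out
}

struct_xyz <- function(s) as.matrix(s[, c("x", "y", "z")])

#' Principal helix axis from backbone coordinates
#'
#' Returns the unit vector along the largest-variance direction of a C-alpha
#' point cloud, with the sign fixed to point from the first toward the last
#' residue (increasing residue index).
#'
#' @param backbone_coords Numeric n x 3 matrix of C-alpha positions, ordered
#'   by residue; at least 4 positions required.
#' @return Unit 3-vector.
#' @export
helix_axis <- function(backbone_coords) {
  m <- as.matrix(backbone_coords)
  if (nrow(m) < 4L)
    stop("need at least 4 C-alpha positions to define a helix axis")
  centred <- sweep(m, 2, colMeans(m))
  v <- svd(centred, nu = 0, nv = 1)$v[, 1]
  if (sum(v * (m[nrow(m), ] - m[1, ])) < 0) v <- -v
  v / sqrt(sum(v^2))
}

# Side-chain tip position for a residue under a tip rule.
# "auto": TIP pseudo-atom if present, else the residue-type rule
# (TRP: six-membered-ring centroid; ARG: guanidinium carbon CZ).
sidechain_tip <- function(res_atoms, tip_rule = "auto") {
  pick <- function(names_needed) {
    hit <- res_atoms[res_atoms$atom %in% names_needed, , drop = FALSE]
    missing <- setdiff(names_needed, hit$atom)
    if (length(missing) > 0)
      stop("missing side-chain atoms: ", paste(missing, collapse = ", "))
    colMeans(struct_xyz(hit))
  }
  if (is.character(tip_rule) && length(tip_rule) == 1 && tip_rule == "auto") {
    if ("TIP" %in% res_atoms$atom) return(pick("TIP"))
    resid <- res_atoms$resid[1]
    if (resid == "TRP")
      return(pick(c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))
    if (resid == "ARG") return(pick("CZ"))
    stop(sprintf("no tip rule for residue %s; supply atom names via tip_rule",
                 resid))
  }
  pick(tip_rule)
}

#' Angle between the helix axis and a side chain
#'
#' Computes the inclination (0-180 degrees) between the helix axis of the
#' chain containing the residue (principal component of its C-alpha trace)
#' and the vector from the residue's C-alpha to its side-chain tip. The
#' default tip rule uses the `TIP` pseudo-atom when present, the
#' six-membered-ring centroid for tryptophan, and the guanidinium carbon CZ
#' for arginine; a character vector of atom names may be supplied instead.
#'
#' @param structure A `"structure_df"`.
#' @param residue_id Residue number of interest.
#' @param tip_rule `"auto"` or atom names whose centroid is the tip.
#' @param chain Chain to analyze (default: the chain containing the
#'   residue).
#' @return Angle in degrees in `[0, 180]`.
#' @export
sidechain_angle <- function(structure, residue_id, tip_rule = "auto",
                            chain = NULL) {
  stopifnot(inherits(structure, "structure_df"))
  res <- structure[structure$resno == residue_id, , drop = FALSE]
  if (nrow(res) == 0) stop(sprintf("residue %d not found", residue_id))
  if (is.null(chain)) chain <- res$chain[1]
  res <- res[res$chain == chain, , drop = FALSE]
  ca <- res[res$atom == "CA", , drop = FALSE]
  if (nrow(ca) == 0)
    stop(sprintf("missing side-chain atoms: CA of residue %d", residue_id))
  bb <- structure[structure$chain == chain & structure$atom == "CA", ,
                  drop = FALSE]
  bb <- bb[order(bb$resno), , drop = FALSE]
  axis <- helix_axis(struct_xyz(bb))
  tip <- sidechain_tip(res, tip_rule)
  v <- tip - as.numeric(struct_xyz(ca)[1, ])
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("side-chain tip coincides with C-alpha")
  cosang <- sum(v * axis) / nv
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Idealized helix / side-chain / partner toy complex
#'
#' Builds a coordinate set emulating the geometry of a recognition helix
#' with its key side chain and an optional partner lobe: an ideal alpha-helix
#' C-alpha trace along z (chain A, rise 1.5 A, 100 degrees/residue, radius
#' 2.3 A), a side-chain tip pseudo-atom (`TIP`) at the mid-helix residue
#' placed at a configured inclination from the *recomputed* helix axis (so
#' [sidechain_angle()] returns the configured angle), and optionally a
#' partner pseudo-atom cloud (chain B, atoms `PRT`) on the side-chain side.
#' The construction is fully deterministic.
#'
#' @param orientation `"N"` (native-like, default 95 degrees) or `"T"`
#'   (tilted, default 45 degrees).
#' @param include_partner Add the partner lobe (default `TRUE`).
#' @param angle Override the orientation's configured angle, degrees.
#' @param n_res Helix length in residues.
#' @param tip_length C-alpha-to-tip distance, Angstrom.
#' @param partner_distance Distance from the tip to the partner-cloud
#'   centre, Angstrom.
#' @return A `"structure_df"`.
#' @export
make_toy_complex <- function(orientation = c("N", "T"), include_partner = TRUE,
                             angle = NULL, n_res = 18, tip_length = 4,
                             partner_distance = 4) {
  orientation <- match.arg(orientation)
  if (is.null(angle)) angle <- if (orientation == "N") 95 else 45
  i <- seq_len(n_res) - 1L
  phase <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(phase), 2.3 * sin(phase), 1.5 * i)
  axis <- helix_axis(ca)
  # orthonormal in-plane direction for the tip
  ref <- c(1, 0, 0)
  if (abs(sum(ref * axis)) > 0.9) ref <- c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  mid <- ceiling(n_res / 2)
  th <- angle * pi / 180
  tip_dir <- cos(th) * axis + sin(th) * u
  tip <- ca[mid, ] + tip_length * tip_dir
  atoms <- c(rep("CA", n_res), "TIP")
  resid <- c(rep("ALA", n_res), "SCH")
  resno <- c(seq_len(n_res), mid)
  chain <- rep("A", n_res + 1L)
  xyz <- rbind(ca, tip)
  resid[mid] <- "SCH"          # the mid residue carries the side chain
  resid[n_res + 1L] <- "SCH"
  if (include_partner) {
    centre <- tip + partner_distance * tip_dir
    # fixed deterministic cloud: small cubic lattice
    offs <- as.matrix(expand.grid(x = c(-1, 0, 1), y = c(-1, 0, 1),
                                  z = c(-1, 0, 1)))
    cloud <- sweep(offs * 1.2, 2, centre, `+`)
    atoms <- c(atoms, rep("PRT", nrow(cloud)))
    resid <- c(resid, rep("PRT", nrow(cloud)))
    resno <- c(resno, rep(1L, nrow(cloud)))
    chain <- c(chain, rep("B", nrow(cloud)))
    xyz <- rbind(xyz, cloud)
  }
  structure_df(atoms, resid, resno, chain, xyz)
}

#' Read / write structures as PDB
#'
#' Thin wrappers around the bio3d PDB reader/writer. Reading a multi-MODEL
#' file returns a list of `"structure_df"` snapshots.
#'
#' @param struct A `"structure_df"`.
#' @param path File path.
#' @return `write_structure_pdb` returns `path` invisibly;
#'   `read_structure_pdb` returns a `"structure_df"` or a list of them for
#'   multi-MODEL files.
#' @export
write_structure_pdb <- function(struct, path) {
  stopifnot(inherits(struct, "structure_df"))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(struct_xyz(struct))),
                   resno = struct$resno, resid = struct$resid,
                   elety = struct$atom, chain = struct$chain)
  invisible(path)
}

#' @rdname write_structure_pdb
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  one <- function(xyz_row) {
    structure_df(pdb$atom$elety, pdb$atom$resid, pdb$atom$resno,
                 pdb$atom$chain, matrix(xyz_row, ncol = 3, byrow = TRUE))
  }
  if (is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L)
    lapply(seq_len(nrow(pdb$xyz)), function(i) one(pdb$xyz[i, ]))
  else
    one(as.numeric(pdb$xyz))
}

#' Non-bonded parameter table
#'
#' Per-atom-name partial charges and Lennard-Jones parameters used by
#' [nonbonded_energy()].
#'
#' @param table Data frame with columns `atom`, `charge_e`, `epsilon_kcal`,
#'   `rmin_half_A`.
#' @return The validated table, class `"nonbonded_params"`.
#' @export
nonbonded_params <- function(table) {
  need <- c("atom", "charge_e", "epsilon_kcal", "rmin_half_A")
  if (!all(need %in% names(table)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (any(table$epsilon_kcal < 0)) stop("epsilon must be non-negative")
  if (anyDuplicated(table$atom)) stop("duplicate atom names in parameters")
  class(table) <- c("nonbonded_params", "data.frame")
  table
}

#' @rdname nonbonded_params
#' @param path CSV file with the same columns.
#' @export
read_params_csv <- function(path) nonbonded_params(utils::read.csv(path))

#' Toy non-bonded parameters
#'
#' Default parameters for the pseudo-atoms of [make_toy_complex()].
#' @export
toy_params <- function() {
  nonbonded_params(data.frame(
    atom = c("CA", "TIP", "PRT"),
    charge_e = c(0, 0.25, -0.25),
    epsilon_kcal = c(0.05, 0.15, 0.12),
    rmin_half_A = c(2.0, 2.1, 2.0)))
}

COULOMB_CONST <- 332.0636  # kcal/mol * A / e^2

#' Pairwise Lennard-Jones + Coulomb interaction energy
#'
#' Sums, over all cross pairs within the cutoff,
#' `eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6) + 332.0636 q_i q_j / (D r)`
#' with Lorentz-Berthelot-style combining (geometric-mean epsilon,
#' arithmetic sum of rmin halves). A plain distance cutoff (default 12 A)
#' stands in for long-range electrostatics; the toy systems are
#' non-periodic.
#'
#' @param struct_a,struct_b Disjoint `"structure_df"` selections.
#' @param params A `"nonbonded_params"` table covering every atom name in
#'   both selections.
#' @param cutoff Pair cutoff in Angstrom (default 12).
#' @param dielectric Relative dielectric constant D (default 1).
#' @return Interaction energy in kcal/mol.
#' @export
nonbonded_energy <- function(struct_a, struct_b, params = toy_params(),
                             cutoff = 12, dielectric = 1) {
  stopifnot(inherits(struct_a, "structure_df"),
            inherits(struct_b, "structure_df"),
            inherits(params, "nonbonded_params"))
  if (cutoff <= 0) stop("cutoff must be positive")
  lookup <- function(atoms) {
    idx <- match(atoms, params$atom)
    if (anyNA(idx))
      stop("missing non-bonded parameters for atoms: ",
           paste(unique(atoms[is.na(idx)]), collapse = ", "))
    params[idx, , drop = FALSE]
  }
  pa <- lookup(struct_a$atom)
  pb <- lookup(struct_b$atom)
  xa <- struct_xyz(struct_a)
  xb <- struct_xyz(struct_b)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 0.1))
    stop("overlapping atoms across the two selections (r < 0.1 A)")
  within <- r <= cutoff
  if (!any(within)) return(0)
  eps <- sqrt(outer(pa$epsilon_kcal, pb$epsilon_kcal))
  rmin <- outer(pa$rmin_half_A, pb$rmin_half_A, `+`)
  qq <- outer(pa$charge_e, pb$charge_e)
  s6 <- (rmin / r)^6
  e_mat <- eps * (s6^2 - 2 * s6) + COULOMB_CONST * qq / (dielectric * r)
  sum(e_mat[within])
}

#' Mean interaction energy over snapshots
#'
#' Arithmetic mean and standard deviation of [nonbonded_energy()] between
#' two chain selections across an ensemble of structure snapshots.
#'
#' @param snapshots List of `"structure_df"` objects.
#' @param chain_a,chain_b Chain identifiers selecting the two groups.
#' @param params,cutoff,dielectric Passed to [nonbonded_energy()].
#' @return List with `mean`, `sd` (NA for a single snapshot), `n` and the
#'   per-snapshot `energies`.
#' @export
average_snapshot_energy <- function(snapshots, chain_a, chain_b,
                                    params = toy_params(), cutoff = 12,
                                    dielectric = 1) {
  if (length(snapshots) < 1L) stop("need at least one snapshot")
  energies <- vapply(snapshots, function(s) {
    stopifnot(inherits(s, "structure_df"))
    nonbonded_energy(s[s$chain == chain_a, , drop = FALSE],
                     s[s$chain == chain_b, , drop = FALSE],
                     params, cutoff, dielectric)
  }, numeric(1))
  list(mean = mean(energies),
       sd = if (length(energies) > 1L) stats::sd(energies) else NA_real_,
       n = length(energies), energies = energies)
}
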