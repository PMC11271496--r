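#' Generate initial training data by random displacement
#'
#' Each returned configuration is the seed with every Cartesian coordinate
#' displaced independently by a uniform draw on `[-max_disp, +max_disp]`,
#' the standard way to seed gas-phase training data before any model
#' exists. Outputs carry the provenance tag `subset = "initial"`.
#'
#' @param seed_config the seed [configuration()].
#' @param max_disp maximum per-component displacement (Angstrom, > 0 unless
#'   `count` copies of the seed itself are wanted, in which case 0 is
#'   allowed).
#' @param count number of configurations to generate.
#' @param rng_seed integer seed; fixed seed gives bit-identical output.
#' @return a [configuration_set()] of `count` displaced copies.
#' @export
random_displace <- function(seed_config, max_disp = 0.1, count = 10L,
                            rng_seed = 1L) {
  stopifnot(inherits(seed_config, "configuration"))
  if (!is.numeric(max_disp) || length(max_disp) != 1L || max_disp < 0) {
    stop("max_disp must be a non-negative scalar")
  }
  count <- as.integer(count)
  if (is.na(count) || count <= 0L) stop("count must be a positive integer")
  if (n_atoms(seed_config) < 1L) stop("seed configuration has no atoms")
  n <- n_atoms(seed_config)
  configs <- withr_seed(rng_seed, {
    lapply(seq_len(count), function(i) {
      d <- matrix(stats::runif(3L * n, -max_disp, max_disp), ncol = 3L)
      configuration(
        species = seed_config$species,
        positions = seed_config$positions + d,
        cell = seed_config$cell, periodic = seed_config$periodic,
        provenance = c(seed_config$provenance, list(subset = "initial"))
      )
    })
  })
  configuration_set(configs, name = "initial",
                    log = sprintf("random_displace max_disp=%g count=%d seed=%d",
                                  max_disp, count, rng_seed))
}

#' Group atoms into molecules by covalent connectivity
#'
#' Two atoms are bonded when their distance is below 1.2 times the sum of
#' their covalent radii (minimum-image distance for periodic systems).
#'
#' @param config a [configuration()].
#' @param scale bond-cutoff scale factor on the covalent-radius sum.
#' @return integer vector of molecule ids (1-based), one per atom.
#' @export
molecule_ids <- function(config, scale = 1.2) {
  n <- n_atoms(config)
  rad <- covalent_radii(config$species)
  d <- pair_distances(config)
  cut <- outer(rad, rad, "+") * scale
  adj <- d < cut & d > 1e-8
  # union-find over the bond graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) {
    for (j in which(adj[i, ] & seq_len(n) > i)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# All pairwise distances, minimum-image under periodicity.
pair_distances <- function(config) {
  pos <- config$positions
  n <- nrow(pos)
  if (config$periodic && !is.null(config$cell)) {
    d <- matrix(0, n, n)
    inv <- solve(config$cell)
    for (i in seq_len(n)) {
      dv <- sweep(pos, 2L, pos[i, ])
      frac <- dv %*% inv
      frac <- frac - round(frac)
      dv <- frac %*% config$cell
      d[i, ] <- sqrt(rowSums(dv^2))
    }
    d
  } else {
    as.matrix(stats::dist(pos))
  }
}

#' Carve a solvent cluster around a solute
#'
#' Extracts the full solute plus every solvent molecule with at least one
#' atom within `r_cluster` of any solute atom. Molecules are always included
#' whole. The solvent-shell radius must be at least the descriptor cutoff of
#' the potential being trained (`r_cluster >= r_cut`), otherwise atoms near
#' the cluster-vacuum interface see artificially truncated environments.
#' Under periodic boundary conditions molecules are unwrapped to the
#' minimum image relative to the solute before carving, and the result is
#' non-periodic.
#'
#' @param snapshot a [configuration()] (periodic or not).
#' @param solute_atom_indices integer indices of the solute atoms.
#' @param r_cluster solvent-shell radius (Angstrom).
#' @param r_cut descriptor/interaction cutoff of the target potential
#'   (Angstrom).
#' @return a non-periodic [configuration()] containing solute + shell.
#' @export
carve_cluster <- function(snapshot, solute_atom_indices, r_cluster, r_cut) {
  stopifnot(inherits(snapshot, "configuration"))
  if (r_cluster < r_cut) {
    stop("r_cluster (", r_cluster, " A) must be no less than the cut-off ",
         "radius r_cut (", r_cut, " A) used for training the potential")
  }
  n <- n_atoms(snapshot)
  solute_atom_indices <- as.integer(solute_atom_indices)
  if (any(solute_atom_indices < 1L) || any(solute_atom_indices > n)) {
    stop("solute atom indices out of range 1..", n)
  }
  mol <- molecule_ids(snapshot)
  pos <- snapshot$positions
  if (snapshot$periodic && !is.null(snapshot$cell)) {
    # unwrap each molecule to the image nearest the solute centroid
    centre <- colMeans(pos[solute_atom_indices, , drop = FALSE])
    inv <- solve(snapshot$cell)
    for (m in unique(mol)) {
      idx <- which(mol == m)
      # make molecule internally whole relative to its first atom
      ref <- pos[idx[1], ]
      dv <- sweep(pos[idx, , drop = FALSE], 2L, ref)
      frac <- dv %*% inv; frac <- frac - round(frac)
      pos[idx, ] <- sweep(frac %*% snapshot$cell, 2L, ref, "+")
      # shift whole molecule to minimum image w.r.t. solute centroid
      com <- colMeans(pos[idx, , drop = FALSE])
      dvc <- matrix(com - centre, 1L)
      fr <- dvc %*% inv; shift <- (fr - round(fr)) %*% snapshot$cell - dvc
      pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2L, as.numeric(shift), "+")
    }
  }
  solute_mols <- unique(mol[solute_atom_indices])
  solvent_atoms <- which(!(mol %in% solute_mols))
  keep_mols <- solute_mols
  if (length(solvent_atoms)) {
    sol_pos <- pos[solute_atom_indices, , drop = FALSE]
    for (m in setdiff(unique(mol), solute_mols)) {
      idx <- which(mol == m)
      dmin <- min(apply(pos[idx, , drop = FALSE], 1L, function(p) {
        min(sqrt(rowSums(sweep(sol_pos, 2L, p)^2)))
      }))
      if (dmin <= r_cluster) keep_mols <- c(keep_mols, m)
    }
  }
  keep <- which(mol %in% keep_mols)
  configuration(
    species = snapshot$species[keep],
    positions = pos[keep, , drop = FALSE],
    periodic = FALSE,
    provenance = c(snapshot$provenance,
                   list(carved = sprintf("r_cluster=%g", r_cluster)))
  )
}

# ---- toy system builders (synthetic study systems) -------------------------

#' Build a single water molecule
#'
#' Equilibrium geometry of the built-in flexible water model (O-H 0.96 A,
#' H-O-H 104.5 degrees), centred at `origin`.
#'
#' @param origin numeric length-3 offset (Angstrom).
#' @return a 3-atom [configuration()] ordered O, H, H.
#' @export
build_water_molecule <- function(origin = c(0, 0, 0)) {
  r0 <- 0.96
  half <- (104.5 / 2) * pi / 180
  pos <- rbind(
    c(0, 0, 0),
    c(r0 * sin(half),  r0 * cos(half), 0),
    c(-r0 * sin(half), r0 * cos(half), 0)
  )
  configuration(c("O", "H", "H"), sweep(pos, 2L, origin, "+"))
}

#' Build a toy water cluster
#'
#' Places `n_mol` water molecules on the sites of a simple cubic lattice
#' (spacing 3.1 A, roughly liquid density) nearest the origin, each with a
#' random rigid orientation. Intended as a starting structure for reference
#' MD or active learning, not as an equilibrated liquid.
#'
#' @param n_mol number of water molecules.
#' @param spacing lattice spacing (Angstrom).
#' @param rng_seed integer seed for the orientations.
#' @return a [configuration()] with atoms ordered O,H,H per molecule.
#' @export
build_water_cluster <- function(n_mol = 27L, spacing = 3.1, rng_seed = 1L) {
  side <- ceiling(n_mol^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))
  grid <- sweep(grid, 2L, colMeans(grid))
  ord <- order(rowSums(grid^2))
  sites <- grid[ord[seq_len(n_mol)], , drop = FALSE] * spacing
  assemble_waters(sites, rng_seed)
}

#' Build a periodic toy water box
#'
#' @param n_side molecules per box edge (total `n_side^3`).
#' @param box_length cubic box edge (Angstrom); default gives roughly
#'   liquid-water density.
#' @param rng_seed integer seed for orientations.
#' @return a periodic [configuration()].
#' @export
build_water_box <- function(n_side = 3L, box_length = n_side * 3.107,
                            rng_seed = 1L) {
  s <- box_length / n_side
  grid <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                z = seq_len(n_side))) - 0.5
  sites <- grid * s
  cf <- assemble_waters(sites, rng_seed)
  configuration(cf$species, cf$positions, cell = diag(3) * box_length,
                periodic = TRUE)
}

assemble_waters <- function(sites, rng_seed) {
  base <- build_water_molecule()$positions
  base <- sweep(base, 2L, colMeans(base))
  withr_seed(rng_seed, {
    blocks <- lapply(seq_len(nrow(sites)), function(i) {
      R <- random_rotation()
      sweep(base %*% t(R), 2L, sites[i, ], "+")
    })
    configuration(rep(c("O", "H", "H"), nrow(sites)), do.call(rbind, blocks))
  })
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}

#' Build the two-bond reactive toy system
#'
#' Four atoms in two diatomic fragments; the two cross-fragment pairs
#' (1,3) and (2,4) are the forming bonds r1 and r2 of the built-in
#' double-well reactive potential. `r_start` sets the initial forming-bond
#' distances (reactant ~3.2 A, transition-state ~2.35 A, product ~1.55 A
#' with default potential parameters).
#'
#' @param r_start initial r1 = r2 distance (Angstrom).
#' @param bond_length intra-fragment bond length (Angstrom).
#' @return a 4-atom [configuration()] of carbons.
#' @export
build_two_bond_system <- function(r_start = 3.2, bond_length = 1.4) {
  configuration(
    rep("C", 4L),
    rbind(
      c(0, 0, 0), c(bond_length, 0, 0),
      c(0, r_start, 0), c(bond_length, r_start, 0)
    )
  )
}
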