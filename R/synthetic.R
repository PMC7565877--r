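# Synthetic structures and trajectories with known ground truth: channel
# phantoms for geometry profiling, continuous-time jump-process diffusion
# for occupancy/transition analysis, and planted base-pair melting series.

#' Channel phantom specification
#'
#' A pseudo-atom tube: rings of atoms placed at a wall radius around a
#' parametric centerline. The analytic clearance on the centerline,
#' wall_radius(s) - atom_radius, is returned as ground truth.
#'
#' @param length total centerline arclength (Angstrom).
#' @param shape "straight" (along z) or "bent" (a 90-degree circular arc in
#'   the xz-plane whose arclength equals `length`).
#' @param wall_radius constant wall radius (Angstrom) or a function of
#'   arclength.
#' @param atom_radius pseudo-atom van der Waals radius (Angstrom).
#' @param atoms_per_ring atoms per wall ring.
#' @param ring_spacing arclength between rings (Angstrom); must not exceed
#'   2 * atom_radius so no probe-sized gap opens between rings.
#' @param seed integer; fixes the deterministic azimuthal offsets.
#' @return a `ChannelPhantomSpec`.
#' @export
channel_phantom_spec <- function(length = 30, shape = c("straight", "bent"),
                                 wall_radius = 4, atom_radius = 1.5,
                                 atoms_per_ring = 16, ring_spacing = 0.75,
                                 seed = 0L) {
  shape <- match.arg(shape)
  wr <- if (is.function(wall_radius)) wall_radius
        else { wr0 <- wall_radius; function(s) rep(wr0, length.out = base::length(s)) }
  stopifnot(length > 0, atom_radius > 0, atoms_per_ring >= 3L,
            ring_spacing > 0)
  if (ring_spacing > 2 * atom_radius)
    stop("ring_spacing must be <= 2 * atom_radius (no escape gaps)")
  structure(list(length = length, shape = shape, wall_radius = wr,
                 atom_radius = atom_radius,
                 atoms_per_ring = as.integer(atoms_per_ring),
                 ring_spacing = ring_spacing, seed = as.integer(seed)),
            class = "ChannelPhantomSpec")
}

# Centerline point and local (tangent, normal, binormal) frame at
# arclength s, closed form for both shapes.
phantom_frame <- function(spec, s) {
  if (spec$shape == "straight") {
    list(point = cbind(0, 0, s),
         tangent = cbind(0, 0, rep(1, length(s))),
         normal = cbind(1, 0, rep(0, length(s))),
         binormal = cbind(0, 1, rep(0, length(s))))
  } else {
    rc <- spec$length / (pi / 2)  # arc radius for a quarter turn
    th <- s / rc
    list(point = cbind(rc * (1 - cos(th)), 0, rc * sin(th)),
         tangent = cbind(sin(th), 0, cos(th)),
         normal = cbind(cos(th), 0, -sin(th)),
         binormal = cbind(0, rep(1, length(s)), 0))
  }
}

#' Build a channel phantom structure
#'
#' Places `atoms_per_ring` pseudo-atoms on rings of radius
#' `wall_radius(s)` around the centerline every `ring_spacing` Angstrom.
#' Deterministic for a fixed seed. If the wall profile dips to or below
#' the atom radius anywhere, the channel is sealed there and a
#' sealed-channel warning reports the plug location.
#'
#' @param spec a [channel_phantom_spec()].
#' @return list: `structure` (a `MolecularStructure`), `centerline`
#'   (function s -> 1 x 3 point), `clearance_truth` (function s ->
#'   analytic centerline clearance), `start`, `target` (centerline
#'   endpoints), `ring_arclengths`, `spec`.
#' @export
make_channel_phantom <- function(spec) {
  stopifnot(inherits(spec, "ChannelPhantomSpec"))
  s <- seq(0, spec$length, by = spec$ring_spacing)
  wall <- spec$wall_radius(s)
  sealed <- wall <= spec$atom_radius
  if (any(sealed))
    warning(sprintf("sealed channel: wall radius <= atom radius near s = %.1f A",
                    s[which(sealed)[1]]))
  fr <- phantom_frame(spec, s)
  m <- spec$atoms_per_ring
  golden <- pi * (3 - sqrt(5))
  rot0 <- 2 * pi * ((as.numeric(spec$seed) * 0.6180339887498949) %% 1)
  xyz <- do.call(rbind, lapply(seq_along(s), function(j) {
    # stagger successive rings so atom rows never align into grooves
    th <- 2 * pi * (seq_len(m) - 1) / m + rot0 + golden * j
    fr$point[j, ][col(matrix(0, m, 3))] +
      wall[j] * (cos(th) %o% fr$normal[j, ] + sin(th) %o% fr$binormal[j, ])
  }))
  n <- nrow(xyz)
  st <- molecular_structure(
    atom_id = seq_len(n), element = "C", atom_name = "C",
    residue_name = "PHA",
    residue_number = rep(seq_along(s), each = m),
    subunit_id = "W", xyz = xyz, vdw_radius = spec$atom_radius)
  truth <- function(sq) spec$wall_radius(sq) - spec$atom_radius
  list(structure = st,
       centerline = function(sq) phantom_frame(spec, sq)$point,
       clearance_truth = truth,
       start = as.vector(phantom_frame(spec, 0)$point),
       target = as.vector(phantom_frame(spec, spec$length)$point),
       ring_arclengths = s, spec = spec)
}

#' A Gaussian constriction wall profile
#'
#' Convenience profile for planting a constriction of known depth and
#' location: base wall radius minus a Gaussian dip.
#'
#' @param base open-channel wall radius (Angstrom).
#' @param min_wall wall radius at the constriction apex (Angstrom).
#' @param at arclength of the apex (Angstrom).
#' @param width Gaussian sigma (Angstrom).
#' @return function of arclength.
#' @export
wall_constriction <- function(base = 4, min_wall = 2.5, at = 15,
                              width = 2) {
  function(s) base - (base - min_wall) * exp(-(s - at)^2 / (2 * width^2))
}

#' Ligand count for a target concentration in a cubic box
#'
#' One conversion ties the synthetic loading to the experimental setup:
#' n = c * N_A * V for a cubic box of the given edge. 15 mM in a nominal
#' 120 Angstrom box gives 16 ligands.
#'
#' @param conc_mM concentration in mmol/L.
#' @param box_edge cubic box edge (Angstrom).
#' @return integer ligand count (rounded).
#' @export
ligands_from_concentration <- function(conc_mM = 15, box_edge = 120) {
  round(conc_mM * 1e-3 * 6.02214076e23 * (box_edge * 1e-10)^3 * 1e3)
}

#' Diffusion jump-model specification
#'
#' Each ligand evolves as an independent continuous-time Markov jump
#' process on the region graph plus a "solvent" state, observed at equally
#' spaced frames (state at sample times — the discretization preserves the
#' stationary distribution exactly). Ligand coordinates are placed at the
#' current region's anchor plus truncated Gaussian jitter, bounded by
#' construction to lie within the contact cutoff of that region's
#' pseudo-atoms and outside every other region's.
#'
#' @param regions character vector of region names (excluding "solvent").
#' @param rates named numeric vector of jump rates (1/ns); names of the
#'   form "from->to" where from/to are region names or "solvent".
#' @param anchors matrix of region anchor coordinates (one row per region,
#'   Angstrom); default a line with 3 * cutoff spacing.
#' @param solvent_anchor 3-vector; default well separated from all anchors.
#' @param n_ligands ligand count; default [ligands_from_concentration()]
#'   at 15 mM.
#' @param frame_interval sampling interval (ns).
#' @param n_frames number of frames.
#' @param jitter Gaussian jitter sigma (Angstrom) before truncation.
#' @param cutoff contact cutoff the construction guarantees (Angstrom).
#' @param region_class named character vector of classes per region
#'   (default all "entry").
#' @param terminal character vector of terminal region names.
#' @param init "stationary" (initial states drawn from the stationary
#'   distribution, keeping time averages unbiased) or a state name all
#'   ligands start in.
#' @param seed integer RNG seed.
#' @return a `DiffusionModelSpec` (with generator matrix `Q` attached).
#' @export
diffusion_model_spec <- function(regions, rates, anchors = NULL,
                                 solvent_anchor = NULL,
                                 n_ligands = ligands_from_concentration(),
                                 frame_interval = 0.1, n_frames = 1000L,
                                 jitter = 1, cutoff = 4,
                                 region_class = NULL,
                                 terminal = character(0),
                                 init = "stationary", seed = 1L) {
  stopifnot(length(regions) >= 1L, n_ligands >= 1L, n_frames >= 1L,
            frame_interval > 0, all(rates >= 0))
  nr <- length(regions)
  if (is.null(anchors))
    anchors <- cbind(3 * cutoff * seq_len(nr), 0, 0)
  anchors <- matrix(as.numeric(anchors), nrow = nr)
  if (is.null(solvent_anchor))
    solvent_anchor <- c(0, 3 * cutoff * (nr + 2), 0)
  # regions must be separable at the cutoff: anchors pairwise > 2*cutoff
  all_anchors <- rbind(anchors, solvent_anchor)
  d <- as.matrix(stats::dist(all_anchors))
  diag(d) <- Inf
  if (min(d) < 2 * cutoff)
    stop("anchors closer than 2 * cutoff: regions would overlap ",
         "(ambiguity error)")
  states <- c(regions, "solvent")
  Q <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  for (nm in names(rates)) {
    ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
    if (length(ft) != 2L || !all(ft %in% states))
      stop("rate name must be 'from->to' over declared states: ", nm)
    Q[ft[1], ft[2]] <- rates[[nm]]
  }
  diag(Q) <- -rowSums(Q)
  if (is.null(region_class))
    region_class <- stats::setNames(rep("entry", nr), regions)
  if (!identical(init, "stationary") && !init %in% states)
    stop("init must be 'stationary' or one of the declared states")
  if (identical(init, "stationary") && all(Q == 0))
    stop("zero-rate model needs an explicit init state")
  structure(list(regions = regions, rates = rates, anchors = anchors,
                 solvent_anchor = as.numeric(solvent_anchor),
                 n_ligands = as.integer(n_ligands),
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 jitter = jitter, cutoff = cutoff,
                 region_class = region_class, terminal = terminal,
                 init = init,
                 seed = as.integer(seed), Q = Q, states = states),
            class = "DiffusionModelSpec")
}

# Region graph implied by a diffusion model: adjacency = nonzero rates.
model_region_graph <- function(model, selections = NULL) {
  regs <- lapply(seq_along(model$regions), function(i) {
    nm <- model$regions[i]
    macro_region(nm, selection = selections[[nm]],
                 region_class = model$region_class[[nm]],
                 terminal = nm %in% model$terminal)
  })
  adj <- list()
  for (nm in names(model$rates)) {
    ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
    if (model$rates[[nm]] > 0 && !"solvent" %in% ft)
      adj[[length(adj) + 1L]] <- ft
  }
  region_graph(regs, unique(lapply(adj, sort)))
}

# Simulate one CTMC path and return the state index at each sample time.
sample_ctmc <- function(Q, init, times) {
  ns <- nrow(Q)
  out <- integer(length(times))
  t_now <- 0
  s_now <- init
  i <- 1L
  repeat {
    rate <- -Q[s_now, s_now]
    t_next <- if (rate > 0) t_now + stats::rexp(1, rate) else Inf
    while (i <= length(times) && times[i] < t_next) {
      out[i] <- s_now
      i <- i + 1L
    }
    if (i > length(times)) break
    p <- Q[s_now, ]
    p[s_now] <- 0
    s_now <- sample.int(ns, 1L, prob = p / sum(p))
    t_now <- t_next
  }
  out
}

# Jitter vector with norm strictly below `bound` (truncated Gaussian).
truncated_jitter <- function(n, sigma, bound) {
  v <- matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
  nrm <- sqrt(rowSums(v^2))
  over <- nrm >= bound
  if (any(over))
    v[over, ] <- v[over, , drop = FALSE] *
      (0.95 * bound / nrm[over])
  v
}

#' Generate a multi-ligand diffusion trajectory with known timeline
#'
#' Builds a pseudo-atom topology (4 atoms per region around each anchor,
#' one phosphorus atom per ligand), simulates each ligand's jump process,
#' and renders frames in which a ligand in region r lies within the
#' contact cutoff of r's atoms and outside all others' — so contact-based
#' occupancy assignment recovers the ground-truth timeline exactly.
#' Initial states are drawn from the stationary distribution, keeping the
#' time-average occupancy unbiased. Deterministic for a fixed seed.
#'
#' @param model a [diffusion_model_spec()].
#' @param selections_out if TRUE (default) also return the per-region
#'   `ResidueSelection`s and the implied `RegionGraph`.
#' @return list: `traj` (a `TrajectoryWindow`), `truth` (a
#'   `LigandStateTimeline`), `graph`, `selections`, `model`.
#' @export
make_diffusion_trajectory <- function(model, selections_out = TRUE) {
  stopifnot(inherits(model, "DiffusionModelSpec"))
  set.seed(model$seed)
  nr <- length(model$regions)
  nl <- model$n_ligands
  nf <- model$n_frames
  # topology: 4 pseudo-atoms per region at anchor +- 0.3 A, 1 atom/ligand
  off <- 0.3 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                     c(-1, -1, 1)) / sqrt(3)
  region_xyz <- do.call(rbind, lapply(seq_len(nr), function(i)
    sweep(off, 2L, model$anchors[i, ], "+")))
  lig_xyz0 <- matrix(rep(model$solvent_anchor, nl), nl, 3, byrow = TRUE)
  topo <- molecular_structure(
    atom_id = seq_len(4L * nr + nl),
    element = c(rep("C", 4L * nr), rep("P", nl)),
    atom_name = c(rep("C", 4L * nr), rep("P", nl)),
    residue_name = c(rep("MRX", 4L * nr), rep("CTP", nl)),
    residue_number = c(rep(seq_len(nr), each = 4L), seq_len(nl)),
    subunit_id = c(rep("R", 4L * nr), rep("L", nl)),
    xyz = rbind(region_xyz, lig_xyz0))
  selections <- stats::setNames(
    lapply(seq_len(nr), function(i)
      residue_selection(entries = list(list(subunit_id = "R",
                                            residue_numbers = i)))),
    model$regions)
  graph <- model_region_graph(model, selections)
  # per-ligand state paths, initial states from the stationary law
  an <- ctmc_analytics(model, nf)
  times <- (seq_len(nf) - 1L) * model$frame_interval
  init <- if (identical(model$init, "stationary"))
    sample.int(length(model$states), nl, replace = TRUE,
               prob = pmax(an$pi, 0))
  else rep(match(model$init, model$states), nl)
  state_idx <- vapply(seq_len(nl), function(l)
    sample_ctmc(model$Q, init[l], times), integer(nf))
  state_idx <- matrix(state_idx, nrow = nf)
  primary <- matrix(model$states[state_idx], nf, nl)
  # jitter bound keeps ligand within cutoff of its region's atoms
  # (atom offset 0.3) and, with anchors > 2*cutoff apart, outside others'
  bound <- min(model$jitter * 3, model$cutoff - 0.5)
  anchors_all <- rbind(model$anchors, model$solvent_anchor)
  lig_rows <- 4L * nr + seq_len(nl)
  frames <- vector("list", nf)
  jit <- lapply(seq_len(nl), function(l)
    truncated_jitter(nf, model$jitter, bound))
  base <- coords(topo)
  for (f in seq_len(nf)) {
    xyz <- base
    for (l in seq_len(nl))
      xyz[lig_rows[l], ] <- anchors_all[state_idx[f, l], ] + jit[[l]][f, ]
    frames[[f]] <- xyz
  }
  traj <- trajectory_window(frames, topo, frame_times = times,
                            ligand_resname = "CTP")
  occupied <- lapply(seq_len(nl), function(l)
    lapply(seq_len(nf), function(f) {
      r <- primary[f, l]
      if (r == "solvent") character(0) else r
    }))
  truth <- new_ligand_state_timeline(primary, occupied, graph, times)
  out <- list(traj = traj, truth = truth, model = model)
  if (selections_out) {
    out$graph <- graph
    out$selections <- selections
  }
  out
}

#' Planted base-pair melting series specification
#'
#' @param registers list of per-register plans: each a list with `label`,
#'   `n_bonds` (2 or 3), `p_melted`, `p_partial` (target fractions,
#'   summing to at most 1).
#' @param n_frames frame count (> 0).
#' @param mode "exact" plants state counts exactly (round(p * n) frames per
#'   state, seeded permutation); "binomial" draws states independently per
#'   frame.
#' @param stratum_fraction fraction of frames in stratum "B" (NULL for an
#'   unstratified series); stratum labels are assigned by seeded
#'   permutation, "A" otherwise.
#' @param stratum_multipliers named numeric c(melted=, partial=): factors
#'   applied to the target fractions within stratum "B" (the conditional
#'   contrast, e.g. a ligand present in the downstream pocket doubling the
#'   melted fraction).
#' @param seed integer RNG seed.
#' @return a `MeltSeriesSpec`.
#' @export
melt_series_spec <- function(registers, n_frames = 1000L,
                             mode = c("exact", "binomial"),
                             stratum_fraction = NULL,
                             stratum_multipliers = c(melted = 1,
                                                     partial = 1),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (n_frames < 1L) stop("n_frames must be positive (spec error)")
  for (r in registers) {
    stopifnot(r$n_bonds %in% c(2L, 3L))
    pm <- r$p_melted; pp <- r$p_partial
    if (pm * stratum_multipliers[["melted"]] +
          pp * stratum_multipliers[["partial"]] > 1 || pm + pp > 1)
      stop("melted + partial fractions exceed 1 (spec error)")
  }
  structure(list(registers = registers, n_frames = as.integer(n_frames),
                 mode = mode, stratum_fraction = stratum_fraction,
                 stratum_multipliers = stratum_multipliers,
                 seed = as.integer(seed)),
            class = "MeltSeriesSpec")
}

plant_states <- function(n, pm, pp, mode) {
  if (mode == "exact") {
    nm <- round(pm * n); np <- round(pp * n)
    states <- c(rep("melted", nm), rep("partial", np),
                rep("associated", n - nm - np))
    sample(states)
  } else {
    sample(c("melted", "partial", "associated"), n, replace = TRUE,
           prob = c(pm, pp, 1 - pm - pp))
  }
}

#' Generate a base-pair distance series with planted states
#'
#' Builds a small topology (per register: `n_bonds` template donor atoms
#' and their non-template partners) and frames whose donor-acceptor
#' distances realize the planted per-frame state: intact bonds at
#' 2.9 +- 0.1 Angstrom, broken bonds at 8 +- 1 Angstrom (clamped to stay
#' on the correct side of any cutoff in [3.4, 4.5]). The exact planted
#' state sequence and stratum labels are returned. Deterministic per seed.
#'
#' @param spec a [melt_series_spec()].
#' @return list: `traj` (a `TrajectoryWindow`), `pairs` (list of
#'   `BasePairDefinition`), `truth` (frames x registers character matrix),
#'   `strata` (per-frame labels or NULL), `spec`.
#' @export
make_basepair_series <- function(spec) {
  stopifnot(inherits(spec, "MeltSeriesSpec"))
  set.seed(spec$seed)
  nf <- spec$n_frames
  nreg <- length(spec$registers)
  strata <- NULL
  if (!is.null(spec$stratum_fraction)) {
    nb <- round(spec$stratum_fraction * nf)
    strata <- sample(c(rep("B", nb), rep("A", nf - nb)))
  }
  # topology: registers stacked along y, bonds along x
  atoms <- list(); pairs <- list(); truth <- matrix("", nf, nreg)
  colnames(truth) <- vapply(spec$registers, `[[`, "", "label")
  aid <- 0L
  base_xyz <- list()
  for (j in seq_len(nreg)) {
    r <- spec$registers[[j]]
    for (b in seq_len(r$n_bonds)) {
      base_xyz[[aid + 1L]] <- c(0, 20 * j, 4 * b)        # template donor
      base_xyz[[aid + 2L]] <- c(2.9, 20 * j, 4 * b)      # non-template
      aid <- aid + 2L
    }
    first <- aid - 2L * r$n_bonds + 1L
    pairs[[j]] <- base_pair_definition(
      r$label, cbind(seq(first, by = 2L, length.out = r$n_bonds),
                     seq(first + 1L, by = 2L, length.out = r$n_bonds)))
  }
  xyz0 <- do.call(rbind, base_xyz)
  topo <- molecular_structure(
    atom_id = seq_len(aid), element = rep(c("N", "N"), aid / 2),
    atom_name = "N1", residue_name = "DG",
    residue_number = rep(seq_len(nreg),
                         times = vapply(spec$registers,
                                        function(r) as.integer(r$n_bonds),
                                        0L) * 2L),
    subunit_id = rep(c("T", "N"), aid / 2), xyz = xyz0)
  # plant per-register states (per stratum when stratified)
  for (j in seq_len(nreg)) {
    r <- spec$registers[[j]]
    if (is.null(strata)) {
      truth[, j] <- plant_states(nf, r$p_melted, r$p_partial, spec$mode)
    } else {
      for (s in c("A", "B")) {
        idx <- which(strata == s)
        if (length(idx) == 0L) next
        mult_m <- if (s == "B") spec$stratum_multipliers[["melted"]] else 1
        mult_p <- if (s == "B") spec$stratum_multipliers[["partial"]] else 1
        truth[idx, j] <- plant_states(length(idx), r$p_melted * mult_m,
                                      r$p_partial * mult_p, spec$mode)
      }
    }
  }
  intact_d <- function(n) pmin(2.9 + stats::runif(n, -0.1, 0.1), 3.35)
  broken_d <- function(n) pmax(8 + stats::rnorm(n), 4.6)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- xyz0
    for (j in seq_len(nreg)) {
      r <- spec$registers[[j]]
      nb <- r$n_bonds
      n_broken <- switch(truth[f, j], associated = 0L, melted = nb,
                         partial = sample.int(nb - 1L, 1L))
      broken <- logical(nb)
      if (n_broken > 0L)
        broken[sample.int(nb, n_broken)] <- TRUE
      d <- numeric(nb)
      d[broken] <- broken_d(sum(broken))
      d[!broken] <- intact_d(sum(!broken))
      xyz[pairs[[j]]$pairs[, 2], 1] <- xyz[pairs[[j]]$pairs[, 1], 1] + d
    }
    frames[[f]] <- xyz
  }
  traj <- trajectory_window(frames, topo, ligand_resname = "none")
  list(traj = traj, pairs = pairs, truth = truth, strata = strata,
       spec = spec)
}
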