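# Per-frame Watson-Crick base-pair association states for downstream DNA
# registers: associated / partially melted / melted, with time-fraction
# summaries optionally stratified by ligand state.

#' Define a base pair by its hydrogen-bonding atom pairs
#'
#' @param label register label, e.g. "i+3".
#' @param pairs 2-column integer matrix of atom row indices into the
#'   topology: column 1 the template-strand donor/acceptor heavy atom,
#'   column 2 its non-template partner. 2 rows for an A:T pair, 3 for G:C.
#' @return a `BasePairDefinition`.
#' @export
base_pair_definition <- function(label, pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || !nrow(pairs) %in% c(2L, 3L))
    stop("pairs must be a 2- or 3-row, 2-column index matrix ",
         "(n_bonds must be 2 for A:T, 3 for G:C)")
  structure(list(label = label, pairs = pairs, n_bonds = nrow(pairs)),
            class = "BasePairDefinition")
}

#' Classify one base pair in one frame
#'
#' A hydrogen bond is intact iff the donor-acceptor heavy-atom distance is
#' at most `bond_cutoff` (no angle term). All bonds intact = "associated";
#' none intact = "melted"; otherwise "partial".
#'
#' @param frame_xyz n x 3 coordinate matrix for the frame.
#' @param pair a `BasePairDefinition`.
#' @param bond_cutoff donor-acceptor distance cutoff (Angstrom),
#'   default 3.5.
#' @return one of "associated", "partial", "melted".
#' @export
classify_pair <- function(frame_xyz, pair, bond_cutoff = 3.5) {
  stopifnot(inherits(pair, "BasePairDefinition"))
  if (max(pair$pairs) > nrow(frame_xyz))
    stop("pair atom index exceeds frame atom count (topology error)")
  a <- frame_xyz[pair$pairs[, 1], , drop = FALSE]
  b <- frame_xyz[pair$pairs[, 2], , drop = FALSE]
  d <- sqrt(rowSums((a - b)^2))
  intact <- sum(d <= bond_cutoff)
  if (intact == pair$n_bonds) "associated"
  else if (intact == 0L) "melted"
  else "partial"
}

#' Classify base-pair states over a trajectory
#'
#' @param traj a `TrajectoryWindow`.
#' @param pairs list of `BasePairDefinition` objects.
#' @param bond_cutoff donor-acceptor distance cutoff (Angstrom).
#' @param strata optional per-frame stratum labels (e.g. whether an NTP
#'   occupies the downstream pocket in that frame), length = frame count.
#' @return a `BasePairStateSeries`: list with `states` (frames x registers
#'   character matrix), `registers`, `strata`, `frame_times`.
#' @export
classify_series <- function(traj, pairs, bond_cutoff = 3.5, strata = NULL) {
  labels <- vapply(pairs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("register labels must be unique")
  if (!is.null(strata) && length(strata) != n_frames(traj))
    stop("strata must have one label per frame")
  states <- vapply(pairs, function(p)
    vapply(traj$frames, classify_pair, "", pair = p,
           bond_cutoff = bond_cutoff),
    character(n_frames(traj)))
  states <- matrix(states, nrow = n_frames(traj),
                   dimnames = list(NULL, labels))
  new_base_pair_state_series(states, strata, traj$frame_times)
}

new_base_pair_state_series <- function(states, strata = NULL,
                                       frame_times = NULL) {
  if (is.null(frame_times)) frame_times <- seq_len(nrow(states)) - 1
  stopifnot(all(states %in% c("associated", "partial", "melted")))
  structure(list(states = states, registers = colnames(states),
                 strata = strata, frame_times = frame_times),
            class = "BasePairStateSeries")
}

#' @export
print.BasePairStateSeries <- function(x, ...) {
  cat(sprintf("BasePairStateSeries: %d frames x %d register(s)%s\n",
              nrow(x$states), ncol(x$states),
              if (is.null(x$strata)) "" else
                sprintf(", %d strata", length(unique(x$strata)))))
  invisible(x)
}

fractions_of <- function(v) {
  n <- length(v)
  c(associated = sum(v == "associated") / n,
    partial = sum(v == "partial") / n,
    melted = sum(v == "melted") / n)
}

#' Melting time fractions per register (and stratum)
#'
#' Per register: the fraction of frames in each association state, and the
#' cumulative partial-plus-full melting fraction. When the series carries
#' stratum labels, fractions are additionally reported per stratum —
#' mirroring conditional quantitation of the form "melting fraction with
#' vs without a ligand in the downstream pocket". Strata with zero frames
#' are absent from the table, not reported as zero.
#'
#' @param series a `BasePairStateSeries`.
#' @return data frame: register, stratum (NA for the unconditional row),
#'   n_frames, f_associated, f_partial, f_melted, f_cumulative_melting.
#' @export
melting_fractions <- function(series) {
  stopifnot(inherits(series, "BasePairStateSeries"),
            nrow(series$states) > 0L)
  rows <- list()
  add <- function(register, stratum, v) {
    fr <- fractions_of(v)
    rows[[length(rows) + 1L]] <<- data.frame(
      register = register, stratum = stratum, n_frames = length(v),
      f_associated = fr[["associated"]], f_partial = fr[["partial"]],
      f_melted = fr[["melted"]],
      f_cumulative_melting = fr[["partial"]] + fr[["melted"]])
  }
  for (reg in series$registers) {
    v <- series$states[, reg]
    add(reg, NA_character_, v)
    if (!is.null(series$strata)) {
      for (s in unique(series$strata)) {
        vs <- v[series$strata == s]
        if (length(vs) > 0L) add(reg, as.character(s), vs)
      }
    }
  }
  do.call(rbind, rows)
}

#' Base flipping into a pocket: per-frame occupancy and dwell lengths
#'
#' Flags each frame "in" iff any heavy atom of the selected base lies
#' within `cutoff` of the pocket region's heavy atoms, and summarizes the
#' in-fraction and the dwell-length distribution of the in/out square wave
#' (stochastic flipping of a downstream base in and out of the pocket).
#'
#' @param traj a `TrajectoryWindow`.
#' @param base_sel `ResidueSelection` for the flipping base.
#' @param pocket a `MacroRegion` (with selection) or a `ResidueSelection`
#'   for the pocket lining.
#' @param cutoff contact distance (Angstrom), default 4.
#' @return list: `in_frame` (logical per frame), `fraction`,
#'   `dwell_in`, `dwell_out` (run lengths in frames).
#' @export
base_flip_occupancy <- function(traj, base_sel, pocket, cutoff = 4) {
  pocket_sel <- if (inherits(pocket, "MacroRegion")) pocket$selection
                else pocket
  bi <- resolve_selection(traj$topology, base_sel, heavy_only = TRUE)
  pi_ <- resolve_selection(traj$topology, pocket_sel, heavy_only = TRUE)
  cutoff2 <- cutoff^2
  in_frame <- vapply(traj$frames, function(xyz) {
    bx <- xyz[bi, , drop = FALSE]
    px <- xyz[pi_, , drop = FALSE]
    d2 <- outer(rowSums(bx^2), rowSums(px^2), "+") - 2 * tcrossprod(bx, px)
    min(d2) <= cutoff2
  }, logical(1))
  r <- rle(in_frame)
  list(in_frame = in_frame, fraction = mean(in_frame),
       dwell_in = r$lengths[r$values],
       dwell_out = r$lengths[!r$values])
}
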