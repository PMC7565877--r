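# Per-frame macro-region occupancy of each ligand, binding propensities,
# transition graphs and loading/exit event detection.

new_ligand_state_timeline <- function(primary, occupied, graph, frame_times,
                                      ligand_ids = NULL) {
  if (is.null(ligand_ids)) ligand_ids <- paste0("L", seq_len(ncol(primary)))
  dimnames(primary) <- list(NULL, ligand_ids)
  structure(list(primary = primary, occupied = occupied,
                 graph = graph, frame_times = frame_times,
                 ligand_ids = ligand_ids),
            class = "LigandStateTimeline")
}

#' @export
print.LigandStateTimeline <- function(x, ...) {
  cat(sprintf("LigandStateTimeline: %d frames x %d ligands over %d regions\n",
              nrow(x$primary), ncol(x$primary), length(x$graph$regions)))
  invisible(x)
}

#' Build a timeline from an authored primary-region sequence
#'
#' Convenience constructor for bookkeeping tests and worked examples: each
#' column of `primary` is one ligand's per-frame primary region ("solvent"
#' for none); the occupied set is the singleton primary region.
#'
#' @param primary character matrix (frames x ligands) of region names or
#'   "solvent"; a vector is taken as a single ligand.
#' @param graph a `RegionGraph` declaring every named region.
#' @param frame_times optional times (ns).
#' @return a `LigandStateTimeline`.
#' @export
timeline_from_primary <- function(primary, graph, frame_times = NULL) {
  if (is.vector(primary)) primary <- matrix(primary, ncol = 1L)
  bad <- setdiff(unique(as.vector(primary)), c(region_names(graph), "solvent"))
  if (length(bad) > 0L)
    stop("primary names not in graph: ", paste(bad, collapse = ", "))
  if (is.null(frame_times)) frame_times <- seq_len(nrow(primary)) - 1
  occupied <- lapply(seq_len(ncol(primary)), function(l)
    lapply(seq_len(nrow(primary)), function(f) {
      r <- primary[f, l]
      if (r == "solvent") character(0) else r
    }))
  new_ligand_state_timeline(primary, occupied, graph, frame_times)
}

#' Assign per-frame macro-region occupancy to each ligand
#'
#' A ligand occupies a region in a frame iff any ligand heavy atom lies
#' within `cutoff` of any region heavy atom. The primary region is the
#' occupied region of greatest depth rank (terminal > infiltration > entry
#' > external); ties go to the region entered most recently, then to graph
#' order. Frames with no occupied region are "solvent".
#'
#' @param traj a `TrajectoryWindow` with resolved ligand groups.
#' @param graph a `RegionGraph` whose regions carry residue selections
#'   resolvable on the trajectory topology.
#' @param cutoff heavy-atom contact distance (Angstrom), default 4.
#' @return a `LigandStateTimeline`.
#' @export
assign_states <- function(traj, graph, cutoff = 4) {
  rn <- region_names(graph)
  ridx <- lapply(graph$regions, function(r) {
    if (is.null(r$selection))
      stop("region ", r$name, " has no residue selection (selection error)")
    idx <- resolve_selection(traj$topology, r$selection, heavy_only = TRUE,
                             quiet = TRUE)
    if (length(idx) == 0L)
      stop("region ", r$name, " matched no atoms (selection error)")
    idx
  })
  heavy <- traj$topology$element != "H"
  lidx <- lapply(traj$ligand_atom_groups, function(g) g[heavy[g]])
  nl <- length(lidx)
  if (nl == 0L) stop("trajectory has no ligand groups")
  nf <- n_frames(traj)
  depth <- region_depth_rank(graph)
  cutoff2 <- cutoff^2
  primary <- matrix("solvent", nf, nl)
  occupied <- lapply(seq_len(nl), function(l) vector("list", nf))
  # entry frame of the current contiguous occupancy run, per ligand/region
  entered_at <- matrix(NA_integer_, nl, length(rn),
                       dimnames = list(NULL, rn))
  for (f in seq_len(nf)) {
    xyz <- traj$frames[[f]]
    for (l in seq_len(nl)) {
      lx <- xyz[lidx[[l]], , drop = FALSE]
      occ <- vapply(ridx, function(ai) {
        rx <- xyz[ai, , drop = FALSE]
        d2 <- outer(rowSums(lx^2), rowSums(rx^2), "+") -
          2 * tcrossprod(lx, rx)
        min(d2) <= cutoff2
      }, logical(1))
      entered_at[l, occ & is.na(entered_at[l, ])] <- f
      entered_at[l, !occ] <- NA_integer_
      occupied[[l]][[f]] <- rn[occ]
      if (any(occ)) {
        cand <- which(occ)
        cand <- cand[depth[cand] == max(depth[cand])]
        if (length(cand) > 1L)
          cand <- cand[entered_at[l, cand] == max(entered_at[l, cand])]
        primary[f, l] <- rn[cand[1L]]
      }
    }
  }
  new_ligand_state_timeline(primary, occupied, graph, traj$frame_times)
}

#' Binding propensities per region and per channel
#'
#' Per region: the mean over frames of the simultaneous occupant count (the
#' time-average number of bound ligands) and the maximum at any one frame.
#' Per channel: the same statistics on the per-frame count over the
#' channel's member regions — by default counting distinct ligand
#' molecules (a ligand touching two member regions counts once), with the
#' contact-sum convention available via `dedup = FALSE`.
#'
#' @param timeline a `LigandStateTimeline`.
#' @param graph a `RegionGraph` (defaults to the timeline's).
#' @param dedup count distinct ligands per channel frame (default TRUE).
#' @return a `PropensityTable`: list with `regions` and `channels` data
#'   frames of (name, mean_bound, max_bound).
#' @export
binding_propensity <- function(timeline, graph = timeline$graph,
                               dedup = TRUE) {
  rn <- region_names(graph)
  nf <- nrow(timeline$primary)
  nl <- ncol(timeline$primary)
  # counts[f, r]: ligands occupying region r at frame f
  counts <- matrix(0L, nf, length(rn), dimnames = list(NULL, rn))
  for (l in seq_len(nl)) {
    occ <- timeline$occupied[[l]]
    for (f in seq_len(nf))
      if (length(occ[[f]]) > 0L)
        counts[f, occ[[f]]] <- counts[f, occ[[f]]] + 1L
  }
  regions <- data.frame(
    region = rn,
    mean_bound = colMeans(counts),
    max_bound = apply(counts, 2L, max),
    row.names = NULL
  )
  chs <- graph_channels(graph)
  channels <- do.call(rbind, lapply(chs, function(ch) {
    mem <- channel_members(graph, ch)
    if (dedup) {
      per_frame <- integer(nf)
      for (l in seq_len(nl)) {
        occ <- timeline$occupied[[l]]
        for (f in seq_len(nf))
          if (any(occ[[f]] %in% mem))
            per_frame[f] <- per_frame[f] + 1L
      }
    } else {
      per_frame <- rowSums(counts[, mem, drop = FALSE])
    }
    data.frame(channel = ch, mean_bound = mean(per_frame),
               max_bound = max(per_frame))
  }))
  structure(list(regions = regions, channels = channels, dedup = dedup),
            class = "PropensityTable")
}

#' @export
print.PropensityTable <- function(x, ...) {
  cat("Binding propensities (time-average / max simultaneous ligands)\n")
  print(x$regions, row.names = FALSE)
  if (!is.null(x$channels) && nrow(x$channels) > 0L) {
    cat("Channel aggregates",
        if (x$dedup) "(distinct ligands per frame)" else "(contact sums)",
        "\n")
    print(x$channels, row.names = FALSE)
  }
  invisible(x)
}

classify_state <- function(graph) {
  cls <- region_classes(graph)
  term <- vapply(graph$regions, `[[`, TRUE, "terminal")
  function(r) {
    if (r == "solvent") "solvent"
    else if (term[[r]]) "terminal"
    else cls[[r]]
  }
}

# Event detection on one ligand's primary-region sequence.
detect_events <- function(s, graph, ligand_id) {
  state_of <- classify_state(graph)
  depth <- region_depth_rank(graph)
  ev <- list()
  emit <- function(kind, deepest, from, to)
    ev[[length(ev) + 1L]] <<- data.frame(
      ligand = ligand_id, kind = kind, deepest_region = deepest,
      frame_start = from, frame_end = to)
  in_inf <- FALSE; deepest <- NA_character_; exc_start <- NA_integer_
  last_deepest <- NA_character_
  was_inf_since_solvent <- FALSE
  close_excursion <- function(t_end) {
    kind <- if (state_of(deepest) == "terminal") "complete_loading"
            else "partial_loading"
    emit(kind, deepest, exc_start, t_end)
    last_deepest <<- deepest
    in_inf <<- FALSE
  }
  for (t in seq_along(s)) {
    r <- s[t]
    cls <- state_of(r)
    if (cls %in% c("infiltration", "terminal")) {
      if (!in_inf) {
        in_inf <- TRUE; exc_start <- t; deepest <- r
      } else if (depth[[r]] > depth[[deepest]]) deepest <- r
      was_inf_since_solvent <- TRUE
    } else {
      if (in_inf) close_excursion(t - 1L)
      if (r == "solvent") {
        if (was_inf_since_solvent)
          emit("exit", last_deepest, t - 1L, t)
        was_inf_since_solvent <- FALSE
      }
    }
    if (t > 1L && s[t - 1L] == "solvent" && cls == "entry")
      emit("entry", r, t - 1L, t)
  }
  if (in_inf) close_excursion(length(s))
  if (length(ev) == 0L) NULL else do.call(rbind, ev)
}

#' Transition graph and loading/exit events
#'
#' Counts primary-region changes as directed edges (including "solvent")
#' and detects events per ligand: `entry` (solvent to an entry region),
#' `partial_loading` (an infiltration excursion that never reaches a
#' terminal region), `complete_loading` (an excursion reaching a terminal
#' region), and `exit` (return to solvent after visiting infiltration).
#' Transitions between regions not adjacent in the graph are kept but
#' flagged with a warning — cutoff-based occupancy can skip a frame.
#'
#' @param timeline a `LigandStateTimeline`.
#' @param graph a `RegionGraph` (defaults to the timeline's).
#' @return a `TransitionGraph`: list with `edges` (data frame: from, to,
#'   count, adjacent) and `events` (data frame: ligand, kind,
#'   deepest_region, frame_start, frame_end; NULL-safe empty data frame
#'   when no events).
#' @export
transition_graph <- function(timeline, graph = timeline$graph) {
  nl <- ncol(timeline$primary)
  trans <- list()
  events <- list()
  for (l in seq_len(nl)) {
    s <- timeline$primary[, l]
    ch <- which(s[-1] != s[-length(s)])
    if (length(ch) > 0L)
      trans[[l]] <- data.frame(from = s[ch], to = s[ch + 1L],
                               ligand = timeline$ligand_ids[l])
    events[[l]] <- detect_events(s, graph, timeline$ligand_ids[l])
  }
  trans <- do.call(rbind, trans)
  if (is.null(trans)) {
    edges <- data.frame(from = character(0), to = character(0),
                        count = integer(0), adjacent = logical(0))
  } else {
    edges <- stats::aggregate(count ~ from + to,
                              data = transform(trans, count = 1L), FUN = sum)
    edges$adjacent <- mapply(function(a, b) {
      if (a == "solvent" || b == "solvent") {
        other <- if (a == "solvent") b else a
        region_classes(timeline$graph)[[other]] %in% c("entry", "external")
      } else are_adjacent(graph, a, b)
    }, edges$from, edges$to)
    if (any(!edges$adjacent))
      warning("transitions between non-adjacent regions observed: ",
              paste(sprintf("%s->%s", edges$from[!edges$adjacent],
                            edges$to[!edges$adjacent]), collapse = ", "))
  }
  events <- do.call(rbind, events)
  if (is.null(events))
    events <- data.frame(ligand = character(0), kind = character(0),
                         deepest_region = character(0),
                         frame_start = integer(0), frame_end = integer(0))
  structure(list(edges = edges, events = events),
            class = "TransitionGraph")
}

#' @export
print.TransitionGraph <- function(x, ...) {
  cat(sprintf("TransitionGraph: %d directed edges, %d events\n",
              nrow(x$edges), nrow(x$events)))
  if (nrow(x$events) > 0L) print(table(x$events$kind))
  invisible(x)
}

#' Farthest reach of each ligand along a pathway axis
#'
#' For each ligand, among the frames where it occupies one of the given
#' member regions, finds the frame minimizing the arclength-to-terminus of
#' the projection of the ligand centroid onto the axis — the apex of its
#' excursion, whether or not it later retreats. Ligands that never occupy a
#' member region are omitted.
#'
#' @param timeline a `LigandStateTimeline`.
#' @param axis a `PathwayAxis` for the channel of interest.
#' @param traj the `TrajectoryWindow` the timeline was computed from.
#' @param regions member region names defining the channel; default all
#'   non-solvent regions in the timeline's graph.
#' @return data frame: ligand, frame, x, y, z (projected axis point),
#'   arclength_from_end.
#' @export
farthest_reach <- function(timeline, axis, traj,
                           regions = region_names(timeline$graph)) {
  heavy <- traj$topology$element != "H"
  out <- list()
  for (l in seq_len(ncol(timeline$primary))) {
    occ <- timeline$occupied[[l]]
    frames <- which(vapply(occ, function(o) any(o %in% regions), TRUE))
    if (length(frames) == 0L) next
    g <- traj$ligand_atom_groups[[l]]
    g <- g[heavy[g]]
    best <- NULL
    for (f in frames) {
      cen <- colMeans(traj$frames[[f]][g, , drop = FALSE])
      pr <- project_on_axis(cen, axis)
      if (is.null(best) || pr$arclength_from_end < best$arclength_from_end)
        best <- c(list(frame = f), pr)
    }
    out[[length(out) + 1L]] <- data.frame(
      ligand = timeline$ligand_ids[l], frame = best$frame,
      x = best$point[1], y = best$point[2], z = best$point[3],
      arclength_from_end = best$arclength_from_end)
  }
  if (length(out) == 0L)
    return(data.frame(ligand = character(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      arclength_from_end = numeric(0)))
  do.call(rbind, out)
}

# Closest point on the axis polyline and its arclength from the terminus.
project_on_axis <- function(p, axis) {
  pts <- axis$points
  arc_end <- axis$arclength_from_end
  best_d2 <- Inf; best_pt <- NULL; best_arc <- NA_real_
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    q <- a + t * ab
    d2 <- sum((p - q)^2)
    if (d2 < best_d2) {
      best_d2 <- d2; best_pt <- q
      best_arc <- arc_end[i] - t * (arc_end[i] - arc_end[i + 1L])
    }
  }
  list(point = best_pt, arclength_from_end = best_arc)
}

#' Compare estimated occupancies against the jump model's analytics
#'
#' Validation of parameter recovery on synthetic diffusion trajectories:
#' per region, compares the timeline's `mean_bound` against the analytic
#' stationary expectation of the continuous-time jump model, with standard
#' errors that account for the autocorrelation of the sampled chain (via
#' the spectral decomposition of the generator), and reports z-scores.
#'
#' @param model a `DiffusionModelSpec` (see [diffusion_model_spec()]).
#' @param timeline a `LigandStateTimeline` computed from a trajectory
#'   generated under `model` (ground truth or re-assigned).
#' @return data frame: region, estimate, expectation, se, z.
#' @export
occupancy_recovery_check <- function(model, timeline) {
  stopifnot(inherits(model, "DiffusionModelSpec"))
  rn <- region_names(timeline$graph)
  if (!setequal(rn, model$regions))
    stop("model/timeline region mismatch (config error)")
  nf <- nrow(timeline$primary)
  prop <- binding_propensity(timeline)
  an <- ctmc_analytics(model, nf)
  est <- prop$regions$mean_bound[match(model$regions, prop$regions$region)]
  expectation <- model$n_ligands * an$pi[model$regions]
  se <- sqrt(model$n_ligands * an$var_mean[model$regions])
  z <- ifelse(se > 0, (est - expectation) / se,
              ifelse(abs(est - expectation) < 1e-12, 0, Inf))
  data.frame(region = model$regions, estimate = est,
             expectation = unname(expectation), se = unname(se),
             z = unname(z), row.names = NULL)
}

# Stationary distribution and variance of the per-ligand time-average
# occupancy indicator for a CTMC sampled at n equally spaced frames.
ctmc_analytics <- function(model, n) {
  states <- c(model$regions, "solvent")
  Q <- model$Q
  delta <- model$frame_interval
  # stationary distribution: left null vector of Q
  ns <- length(states)
  if (all(Q == 0)) {
    # frozen chain: the occupancy law is the (required) explicit init state
    pi_vec <- stats::setNames(as.numeric(states == model$init), states)
    return(list(pi = pi_vec, var_mean = stats::setNames(rep(0, ns), states)))
  }
  A <- rbind(t(Q), rep(1, ns))
  b <- c(rep(0, ns), 1)
  pi_vec <- tryCatch(as.vector(qr.solve(A, b)), error = function(e)
    stop("stationary distribution is not unique; every region must be ",
         "connected through solvent", call. = FALSE))
  names(pi_vec) <- states
  pi_vec[abs(pi_vec) < 1e-15] <- 0
  eg <- eigen(Q)
  V <- eg$vectors; lam <- eg$values
  Vinv <- solve(V)
  var_mean <- numeric(ns)
  names(var_mean) <- states
  lvec <- seq_len(n - 1)
  for (r in seq_len(ns)) {
    p <- pi_vec[r]
    c0 <- p * (1 - p)
    if (c0 == 0 || n == 1L) { var_mean[r] <- 0; next }
    # Cov(1_r(0), 1_r(l*delta)) = pi_r * (P_l)_{rr} - pi_r^2
    a_k <- V[r, ] * Vinv[, r]
    prr <- vapply(lvec, function(l) Re(sum(a_k * exp(lam * delta * l))),
                  numeric(1))
    cl <- p * prr - p^2
    var_mean[r] <- (n * c0 + 2 * sum((n - lvec) * cl)) / n^2
  }
  list(pi = pi_vec, var_mean = pmax(var_mean, 0))
}
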