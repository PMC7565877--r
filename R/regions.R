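# Macro-regions: named residue patches tiling the ligand diffusion
# pathways. Entry regions are reachable directly from solvent, infiltration
# regions only through entry regions; terminal infiltration regions are the
# ultimate diffusion areas (the downstream pocket and the active site).

#' Define a macro-region
#'
#' @param name region name (e.g. "MR1").
#' @param selection a `ResidueSelection` naming the region's residues, or
#'   NULL as a placeholder to be filled in from user data.
#' @param region_class one of "entry", "infiltration", "external".
#' @param channels character vector of channel memberships (subset of
#'   CH2, CH3A, CH3B, CH3C, CH3D).
#' @param terminal logical; TRUE for the ultimate diffusion areas (the
#'   downstream pocket and the active-site region). Reaching a terminal
#'   region is what distinguishes complete from partial loading.
#' @return a `MacroRegion`.
#' @export
macro_region <- function(name, selection = NULL,
                         region_class = c("entry", "infiltration",
                                          "external"),
                         channels = character(0), terminal = FALSE) {
  region_class <- match.arg(region_class)
  if (terminal && region_class != "infiltration")
    stop("terminal regions must be infiltration regions")
  structure(list(name = name, selection = selection,
                 region_class = region_class,
                 channels = as.character(channels),
                 terminal = isTRUE(terminal)),
            class = "MacroRegion")
}

#' Assemble a region graph
#'
#' @param regions list of [macro_region()] objects with unique names.
#' @param adjacency list of length-2 character vectors, each an unordered
#'   pair of adjacent region names. Solvent adjacency is implicit: every
#'   entry and external region borders solvent.
#' @return a `RegionGraph`.
#' @export
region_graph <- function(regions, adjacency = list()) {
  names(regions) <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(names(regions))) stop("region names must be unique")
  for (p in adjacency) {
    if (length(p) != 2L || !all(p %in% names(regions)))
      stop("adjacency pairs must name two declared regions")
  }
  structure(list(regions = regions, adjacency = adjacency),
            class = "RegionGraph")
}

#' @export
print.RegionGraph <- function(x, ...) {
  cls <- vapply(x$regions, `[[`, "", "region_class")
  cat(sprintf(
    "RegionGraph: %d regions (%d entry, %d infiltration, %d external), %d adjacencies\n",
    length(x$regions), sum(cls == "entry"), sum(cls == "infiltration"),
    sum(cls == "external"), length(x$adjacency)))
  invisible(x)
}

region_names <- function(graph) names(graph$regions)

region_classes <- function(graph)
  vapply(graph$regions, `[[`, "", "region_class")

# Depth ranking used to pick the primary region when a ligand touches
# several at once: solvent/external < entry < infiltration < terminal.
region_depth_rank <- function(graph) {
  vapply(graph$regions, function(r) {
    if (r$terminal) 3L
    else switch(r$region_class, external = 0L, entry = 1L,
                infiltration = 2L)
  }, integer(1))
}

graph_channels <- function(graph) {
  sort(unique(unlist(lapply(graph$regions, `[[`, "channels"))))
}

#' Member regions of a channel
#' @param graph a `RegionGraph`.
#' @param channel channel name (e.g. "CH2").
#' @return character vector of member region names.
#' @export
channel_members <- function(graph, channel) {
  names(Filter(function(r) channel %in% r$channels, graph$regions))
}

are_adjacent <- function(graph, a, b) {
  for (p in graph$adjacency)
    if ((p[1] == a && p[2] == b) || (p[1] == b && p[2] == a)) return(TRUE)
  FALSE
}

#' The bundled polymerase macro-region topology
#'
#' Loads the MR1-MR20 map shipped with the package: twenty regions tiling
#' the substrate diffusion pathways of a multi-subunit RNA polymerase.
#' MR1-MR12 are entry regions reachable directly from solvent; MR13 lies
#' externally and bridges MR3 and MR12; MR14-MR20 are infiltration regions
#' reachable only through entry regions, with MR19 (the downstream pocket)
#' and MR20 (the active-site region) terminal. Channel memberships follow
#' the propensity-aggregate convention: CH2 = MR1/2/3/4/14, CH3A = MR5/15,
#' CH3B = MR6/7/16, CH3C = MR8/9/17, CH3D = MR10/11/12/18.
#'
#' Residue selections are shipped as empty placeholders (the concrete
#' residue lists are system-specific); supply them via `selections`.
#'
#' @param selections optional named list of `ResidueSelection` objects,
#'   names matching region names.
#' @return a `RegionGraph`.
#' @export
default_region_graph <- function(selections = NULL) {
  path <- system.file("extdata", "macro_regions.json", package = "ntpflow",
                      mustWork = TRUE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  regions <- lapply(cfg$regions, function(r) {
    sel <- if (!is.null(selections) && r$name %in% names(selections))
      selections[[r$name]] else NULL
    macro_region(r$name, selection = sel, region_class = r$class,
                 channels = unlist(r$channels), terminal = isTRUE(r$terminal))
  })
  adjacency <- lapply(cfg$adjacency, unlist)
  region_graph(regions, adjacency)
}
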