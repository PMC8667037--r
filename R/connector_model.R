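#' Docking-site design on the origami monomer
#'
#' Describes the single-stranded staple extensions that repeat connectors
#' hybridize to. The default is the 7-nt oligo-A extension presented at four
#' sites per cross-linking edge, with two linkable edges per monomer (a
#' geometry that favours linear filaments).
#'
#' @param motif_base Single nucleotide letter of the homopolymer docking
#'   motif (default "A").
#' @param extension_length Length of the docking extension in nucleotides.
#' @param sites_per_edge Number of docking extensions per cross-linking edge.
#' @param linkable_edges Number of edges per monomer that can cross-link
#'   (1 or 2).
#' @return An object of class `docking_spec`.
#' @export
docking_spec <- function(motif_base = "A", extension_length = 7L,
                         sites_per_edge = 4L, linkable_edges = 2L) {
  stopifnot(is.character(motif_base), nchar(motif_base) == 1L)
  extension_length <- as.integer(extension_length)
  sites_per_edge <- as.integer(sites_per_edge)
  linkable_edges <- as.integer(linkable_edges)
  if (extension_length < 1L) stop("extension_length must be >= 1")
  if (sites_per_edge < 1L) stop("sites_per_edge must be >= 1")
  if (!linkable_edges %in% c(1L, 2L)) stop("linkable_edges must be 1 or 2")
  structure(
    list(motif_base = motif_base, extension_length = extension_length,
         sites_per_edge = sites_per_edge, linkable_edges = linkable_edges),
    class = "docking_spec")
}

#' Connector-strand design
#'
#' A connector cross-links two origami monomers. Scaffold connectors bind
#' scaffold loops directly and are site- and orientation-specific. Repeat
#' connectors are low-complexity strands (e.g. oligo-T, possibly with an
#' internal non-binding oligo-C spacer) that bind the homopolymer docking
#' extensions in any of several reading frames.
#'
#' @param kind "scaffold" or "repeat".
#' @param total_length Total connector length in nucleotides.
#' @param sticker_length Length in nucleotides of each terminal binding
#'   stretch ("sticker"). For all-T connectors without a spacer any register
#'   along the strand can bind, so the effective per-end binding length is
#'   the total length; pass `sticker_length = total_length` and
#'   `spacer_length = 0` for those.
#' @param spacer_length Length of the internal non-binding stretch (0 for
#'   all-T connectors).
#' @param concentration Connector concentration in nM.
#' @param orientation_specific Whether binding requires a particular mutual
#'   monomer orientation (always `TRUE` for scaffold connectors).
#' @param flexible_linker Scaffold-connector variant carrying a short
#'   flexible linker between its binding sites.
#' @param label Optional condition label.
#' @return An object of class `connector_spec`.
#' @export
connector_spec <- function(kind = c("repeat", "scaffold"),
                           total_length,
                           sticker_length = total_length,
                           spacer_length = 0L,
                           concentration = 250,
                           orientation_specific = (kind == "scaffold"),
                           flexible_linker = FALSE,
                           label = NULL) {
  kind <- match.arg(kind)
  total_length <- as.integer(total_length)
  sticker_length <- as.integer(sticker_length)
  spacer_length <- as.integer(spacer_length)
  if (sticker_length > total_length)
    stop("sticker_length must not exceed total_length")
  if (spacer_length > 0L && total_length != 2L * sticker_length + spacer_length)
    stop("with a spacer, total_length must equal 2*sticker_length + spacer_length")
  if (concentration <= 0) stop("concentration must be > 0")
  if (kind == "scaffold" && !orientation_specific)
    stop("scaffold connectors are orientation-specific")
  if (is.null(label)) {
    label <- if (kind == "scaffold") {
      if (flexible_linker) "scaffold+linker" else "scaffold"
    } else if (spacer_length > 0L) {
      sprintf("sticker%dnt", sticker_length)
    } else {
      sprintf("T%d", total_length)
    }
  }
  structure(
    list(kind = kind, total_length = total_length,
         sticker_length = sticker_length, spacer_length = spacer_length,
         concentration = concentration,
         orientation_specific = orientation_specific,
         flexible_linker = flexible_linker, label = label),
    class = "connector_spec")
}

#' Effective-association-rate model
#'
#' Parameters of the product-form rate law used to turn a connector design
#' into an effective hybridization on-rate: a base on-rate for a single
#' perfectly matched register, a hairpin-accessibility factor in (0, 1]
#' penalizing sequences that fold back on themselves (relevant for scaffold
#' connectors; low-complexity repeats cannot form hairpins), and a valence
#' multiplier for edges presenting several docking sites.
#'
#' @param base_on_rate Hybridization on-rate of one matched register, in
#'   per-molar per-second.
#' @param hairpin_accessibility Fraction of connectors not sequestered in
#'   secondary structure, in (0, 1]. This is an input parameter; no
#'   sequence-level structure prediction is performed.
#' @param valence_multiplier Multiplicative factor >= 1 for multi-site edges.
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(base_on_rate = 1e6, hairpin_accessibility = 1,
                       valence_multiplier = 1) {
  if (base_on_rate <= 0) stop("base_on_rate must be > 0")
  if (hairpin_accessibility <= 0 || hairpin_accessibility > 1)
    stop("hairpin_accessibility must be in (0, 1]")
  if (valence_multiplier < 1) stop("valence_multiplier must be >= 1")
  structure(
    list(base_on_rate = base_on_rate,
         hairpin_accessibility = hairpin_accessibility,
         valence_multiplier = valence_multiplier),
    class = "rate_model")
}

#' Number of binding reading frames
#'
#' Counts the alignment registers at which a docking extension of
#' `docking_length` nucleotides is fully covered by a homopolymer sticker of
#' `sticker_length` nucleotides: `max(0, sticker_length - docking_length + 1)`.
#' A 9-nt sticker offers 3 frames against the 7-nt docking extension, an 8-nt
#' sticker 2, and a 6-nt sticker none (it cannot fully hybridize the site).
#'
#' @param sticker_length Sticker length in nucleotides (>= 1).
#' @param docking_length Docking-extension length in nucleotides (>= 1).
#' @return Integer count of reading frames (possibly 0).
#' @export
reading_frames <- function(sticker_length, docking_length) {
  sticker_length <- as.integer(sticker_length)
  docking_length <- as.integer(docking_length)
  if (any(sticker_length < 1L) || any(docking_length < 1L))
    stop("lengths must be positive")
  pmax(0L, sticker_length - docking_length + 1L)
}

#' Maximum simultaneous docking-site occupancy of one connector
#'
#' Overlapping registers on the same connector compete: two docking
#' extensions can only be engaged at the same time if their footprints on the
#' connector do not overlap. The maximum is
#' `floor(connector_binding_length / docking_length)`.
#'
#' @param connector_binding_length Length in nucleotides of the connector
#'   stretch available for binding.
#' @param docking_length Docking-extension length in nucleotides.
#' @return Integer count of simultaneously engageable docking extensions.
#' @export
max_simultaneous_occupancy <- function(connector_binding_length,
                                       docking_length) {
  connector_binding_length <- as.integer(connector_binding_length)
  docking_length <- as.integer(docking_length)
  if (any(connector_binding_length < 1L) || any(docking_length < 1L))
    stop("lengths must be positive")
  connector_binding_length %/% docking_length
}

#' Effective association rate of a connector design
#'
#' Product-form rate law
#' `k_eff = base_on_rate * frames * hairpin_accessibility * valence_multiplier`,
#' the simplest law consistent with the two mechanisms driving assembly
#' acceleration: multiple binding reading frames raise the effective local
#' concentration of binding sites, and low-complexity sequences avoid the
#' hairpin penalty of scaffold-loop-binding connectors. Scaffold connectors
#' have a single defined register (`frames = 1`); repeat connectors derive
#' their frame count from the sticker length (the full strand length for
#' spacer-free all-T connectors, where any register can serve either binding
#' partner).
#'
#' @param model A [rate_model()].
#' @param connector A [connector_spec()].
#' @param docking A [docking_spec()].
#' @return Effective on-rate in per-molar per-second; 0 when the sticker is
#'   too short to offer any reading frame.
#' @export
effective_on_rate <- function(model, connector, docking = docking_spec()) {
  stopifnot(inherits(model, "rate_model"),
            inherits(connector, "connector_spec"),
            inherits(docking, "docking_spec"))
  frames <- if (connector$kind == "scaffold") {
    1L
  } else {
    binding_len <- if (connector$spacer_length > 0L)
      connector$sticker_length else connector$total_length
    reading_frames(binding_len, docking$extension_length)
  }
  if (frames == 0L) return(0)
  model$base_on_rate * frames * model$hairpin_accessibility *
    model$valence_multiplier
}

#' Per-edge-pair link rate for the simulator
#'
#' Folds the effective on-rate and the connector concentration into the
#' single first-order rate at which an eligible edge pair in contact forms a
#' bond. Connectors are coarse-grained: they are not explicit particles.
#'
#' @param model A [rate_model()].
#' @param connector A [connector_spec()] (its `concentration`, in nM, is
#'   used).
#' @param docking A [docking_spec()].
#' @return Link rate in per-second.
#' @export
link_rate_from_connector <- function(model, connector,
                                     docking = docking_spec()) {
  k_eff <- effective_on_rate(model, connector, docking)
  k_eff * connector$concentration * 1e-9
}

#' @export
print.connector_spec <- function(x, ...) {
  cat(sprintf("<connector_spec> %s: %s, %d nt total, %d nt sticker, %d nt spacer, %g nM\n",
              x$label, x$kind, x$total_length, x$sticker_length,
              x$spacer_length, x$concentration))
  invisible(x)
}
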