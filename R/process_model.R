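#' Biorefinery design basis
#'
#' The design basis fixes the annual silage processing capacity and the
#' per-100-g product yields from which every annual stream is derived.
#' Defaults are the base-case design: 33,333 t/y of silage processed, a
#' theoretical-maximum protein recovery of 15 g protein per 100 g silage
#' (giving the 5,000 t/y protein target), 10 g/100 g lipid-rich yeast,
#' 12 g/100 g lignin, and 28,500 t/y of dry solids routed to anaerobic
#' digestion (the printed mass-balance value, kept as stated rather than
#' recomputed as capacity minus protein).
#'
#' @param silage_capacity wet-equivalent silage processing capacity, t/y.
#' @param protein_extraction_efficiency g protein recovered per 100 g
#'   silage (the model's single protein-yield knob, swept in sensitivity).
#' @param lipid_yield g lipid-rich yeast biomass per 100 g silage
#'   (scenario 2 only).
#' @param lignin_yield g lignin per 100 g silage.
#' @param ad_solids dry solid residue sent to anaerobic digestion, t/y.
#' @return object of class `design_basis`.
#' @export
design_basis <- function(silage_capacity = 33333,
                         protein_extraction_efficiency = 15,
                         lipid_yield = 10,
                         lignin_yield = 12,
                         ad_solids = 28500) {
  vals <- c(silage_capacity = silage_capacity,
            protein_extraction_efficiency = protein_extraction_efficiency,
            lipid_yield = lipid_yield, lignin_yield = lignin_yield,
            ad_solids = ad_solids)
  storage.mode(vals) <- "double"
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all design-basis values must be finite and >= 0", call. = FALSE)
  if (protein_extraction_efficiency > 100)
    stop("protein_extraction_efficiency cannot exceed 100 g/100 g",
         call. = FALSE)
  structure(as.list(vals), class = "design_basis")
}

#' @export
print.design_basis <- function(x, ...) {
  cat("<design_basis>\n")
  cat(sprintf("  silage capacity: %s t/y\n",
              format(x$silage_capacity, big.mark = ",")))
  cat(sprintf("  protein extraction: %g g/100 g; lipid: %g; lignin: %g\n",
              x$protein_extraction_efficiency, x$lipid_yield, x$lignin_yield))
  cat(sprintf("  AD solids: %s t/y\n", format(x$ad_solids, big.mark = ",")))
  invisible(x)
}

#' Extraction-stage yield set
#'
#' Diagnostic stream-split parameters from the mechanochemical extraction
#' trials: the solubilised mass fraction, the share of total protein
#' recovered in the liquid phase, the dry-basis protein purity of the
#' membrane concentrate, and the crude protein content of dry silage. These
#' describe the front-end split; revenue calculations are driven by the
#' design-basis extraction efficiency, not by this set.
#'
#' @param solubilized_fraction wt fraction of biomass solubilised (0.22).
#' @param protein_liquid_recovery fraction of total protein recovered in the
#'   liquid phase (0.52).
#' @param concentrate_purity wt fraction protein in the concentrate, dry
#'   basis (0.60).
#' @param crude_protein_content wt fraction protein in dry silage (0.15).
#' @return object of class `yield_set`.
#' @export
yield_set <- function(solubilized_fraction = 0.22,
                      protein_liquid_recovery = 0.52,
                      concentrate_purity = 0.60,
                      crude_protein_content = 0.15) {
  vals <- c(solubilized_fraction, protein_liquid_recovery,
            concentrate_purity, crude_protein_content)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("all yields must lie in [0, 1]", call. = FALSE)
  structure(list(solubilized_fraction = solubilized_fraction,
                 protein_liquid_recovery = protein_liquid_recovery,
                 concentrate_purity = concentrate_purity,
                 crude_protein_content = crude_protein_content),
            class = "yield_set")
}

stream_table <- function(streams) {
  stopifnot(is.numeric(streams), !is.null(names(streams)))
  if (any(streams < -1e-9)) stop("stream masses must be >= 0", call. = FALSE)
  structure(data.frame(stream = names(streams),
                       mass_tpy = as.numeric(pmax(streams, 0)),
                       row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("stream_table", "data.frame"))
}

#' Look up a stream's annual mass
#'
#' @param tab a `stream_table`.
#' @param id stream id; absent streams return 0 t/y.
#' @return annual mass, t/y.
#' @export
stream_mass <- function(tab, id) {
  i <- match(id, tab$stream)
  if (is.na(i)) 0 else tab$mass_tpy[i]
}

#' Annual product rates for a scenario
#'
#' Converts the design basis into annual sellable product streams:
#' `protein_product = capacity * e/100`, `lignin = capacity * lignin_yield/100`,
#' `lipid_rich_yeast = capacity * lipid_yield/100` for scenarios that include
#' the fermentation stage (else 0), and the AD solids stream as stated in the
#' basis.
#'
#' @param basis a [design_basis()].
#' @param scenario scenario name (`"scenario1"`, `"scenario2"`) or a scenario
#'   definition with an `includes_fermentation` flag.
#' @return a `stream_table` data frame (stream, mass_tpy).
#' @examples
#' product_rates(design_basis(), "scenario1")  # protein 5,000 t/y
#' @export
product_rates <- function(basis, scenario = "scenario1") {
  stopifnot(inherits(basis, "design_basis"))
  ferm <- if (is.list(scenario)) isTRUE(scenario$includes_fermentation)
          else identical(scenario, "scenario2")
  cap <- basis$silage_capacity
  stream_table(c(
    protein_product  = cap * basis$protein_extraction_efficiency / 100,
    lipid_rich_yeast = if (ferm) cap * basis$lipid_yield / 100 else 0,
    lignin           = cap * basis$lignin_yield / 100,
    ad_solids        = basis$ad_solids))
}

#' Front-end extraction stream split
#'
#' Applies the extraction-stage yield set to the processing capacity:
#' the solubilised liquid fraction, the protein recovered into it
#' (`capacity * crude_protein_content * protein_liquid_recovery`), the
#' concentrate mass implied by the dry-basis purity, and the solid residue
#' (capacity minus liquid, exact mass conservation).
#'
#' @param basis a [design_basis()].
#' @param yields a [yield_set()].
#' @return a `stream_table` with streams `liquid_fraction`,
#'   `recovered_protein`, `protein_concentrate`, `solid_residue`.
#' @export
extraction_streams <- function(basis, yields = yield_set()) {
  stopifnot(inherits(basis, "design_basis"), inherits(yields, "yield_set"))
  if (yields$concentrate_purity == 0)
    stop("concentrate_purity = 0: concentrate mass undefined", call. = FALSE)
  cap <- basis$silage_capacity
  liquid <- cap * yields$solubilized_fraction
  protein <- cap * yields$crude_protein_content * yields$protein_liquid_recovery
  stream_table(c(
    liquid_fraction     = liquid,
    recovered_protein   = protein,
    protein_concentrate = protein / yields$concentrate_purity,
    solid_residue       = cap - liquid))
}

#' Rescale the design basis to a protein production target
#'
#' Returns a basis whose capacity is `target_protein * 100 / e`; all
#' yield-proportional streams rescale linearly, and the AD solids stream
#' scales by the same capacity ratio.
#'
#' @param basis a [design_basis()].
#' @param target_protein desired protein output, t/y (> 0).
#' @return a rescaled `design_basis`.
#' @examples
#' scale_design(design_basis(), 10000)$silage_capacity  # 66,667 t/y
#' @export
scale_design <- function(basis, target_protein) {
  stopifnot(inherits(basis, "design_basis"))
  e <- basis$protein_extraction_efficiency
  if (e <= 0) stop("cannot scale a basis with zero extraction efficiency",
                   call. = FALSE)
  if (target_protein <= 0) stop("target_protein must be > 0", call. = FALSE)
  new_cap <- target_protein * 100 / e
  ratio <- new_cap / basis$silage_capacity
  design_basis(silage_capacity = new_cap,
               protein_extraction_efficiency = e,
               lipid_yield = basis$lipid_yield,
               lignin_yield = basis$lignin_yield,
               ad_solids = basis$ad_solids * ratio)
}
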