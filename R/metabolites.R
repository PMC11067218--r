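#' Canonical metabolite panel
#'
#' The 28 plasma metabolites of the targeted LC-MS/MS panel: the twenty
#' proteinogenic amino acids, the urea-cycle metabolites Ornithine and
#' Citrulline, the sulfur-containing metabolites Cystathionine, Homocysteine,
#' Taurine and Glutathione, the derivative alpha-Aminobutyric acid
#' (Homoalanine), and Creatinine. All tabular inputs are aligned to this
#' column order.
#'
#' @return Character vector of 28 metabolite names.
#' @export
periamp_metabolites <- function() {
  c("Alanine", "Arginine", "Asparagine", "Aspartic acid", "Cysteine",
    "Glutamic acid", "Glutamine", "Glycine", "Histidine", "Isoleucine",
    "Leucine", "Lysine", "Methionine", "Phenylalanine", "Proline", "Serine",
    "Threonine", "Tryptophan", "Tyrosine", "Valine",
    "Ornithine", "Citrulline", "Cystathionine", "Homocysteine", "Taurine",
    "Glutathione", "alpha-Aminobutyric acid", "Creatinine")
}

#' Metabolites reduced in malignant disease (default planted effects)
#'
#' The fifteen panel metabolites observed at lower plasma levels in
#' periampullary cancer: the essential amino acids Histidine, Lysine and
#' Threonine, the BCAA family (Isoleucine, Leucine, Valine), the
#' non-essential Alanine, Asparagine, Glutamine, Glycine, Proline and Serine,
#' plus alpha-Aminobutyric acid, Ornithine and Citrulline. Glutamic acid is
#' the single metabolite elevated in malignancy.
#'
#' @return Character vector of 15 metabolite names.
#' @export
periamp_effect_metabolites <- function() {
  c("Histidine", "Lysine", "Threonine", "Isoleucine", "Leucine", "Valine",
    "Alanine", "Asparagine", "Glutamine", "Glycine", "Proline", "Serine",
    "alpha-Aminobutyric acid", "Ornithine", "Citrulline")
}

# Plausible plasma concentration locations (approx. micromolar medians,
# log2 scale) and heterogeneous log2-scale spreads. Cysteine is given the
# narrowest and Cystathionine the widest range, mirroring the spread pattern
# of targeted amino-acid panels.
metabolite_log2_location <- function(metabolites = periamp_metabolites()) {
  um <- c(
    "Alanine" = 350, "Arginine" = 80, "Asparagine" = 50, "Aspartic acid" = 5,
    "Cysteine" = 30, "Glutamic acid" = 50, "Glutamine" = 550, "Glycine" = 230,
    "Histidine" = 80, "Isoleucine" = 60, "Leucine" = 120, "Lysine" = 180,
    "Methionine" = 25, "Phenylalanine" = 60, "Proline" = 180, "Serine" = 110,
    "Threonine" = 130, "Tryptophan" = 50, "Tyrosine" = 60, "Valine" = 220,
    "Ornithine" = 60, "Citrulline" = 30, "Cystathionine" = 0.2,
    "Homocysteine" = 10, "Taurine" = 60, "Glutathione" = 5,
    "alpha-Aminobutyric acid" = 20, "Creatinine" = 70)
  log2(um[metabolites])
}

metabolite_log2_scale <- function(metabolites = periamp_metabolites()) {
  s <- rep(0.45, length(metabolites))
  names(s) <- metabolites
  s[names(s) == "Cysteine"] <- 0.15
  s[names(s) == "Cystathionine"] <- 1.10
  s[names(s) == "Glutathione"] <- 0.80
  s[names(s) == "Homocysteine"] <- 0.60
  s[names(s) == "Taurine"] <- 0.55
  s
}
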