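#' Published per-residue thermodynamic parameters for Yfh1
#'
#' The per-residue two-state unfolding parameters and RAD burial scores of
#' yeast frataxin (Yfh1), compiled from the published site-specific
#' 15N-HSQC melting analysis of the protein (68 backbone amides plus the
#' Trp131 side-chain indole; structure numbering of PDB 2fql). Columns:
#' `residue_label`, `dH_kcal_mol` (unfolding enthalpy at Tm),
#' `dS_kcal_mol_K` (unfolding entropy at Tm), `dCp_kcal_mol_K`, `Tm_K`,
#' `Tc_K`, `RAD` (burial score; `NA` where not reported).
#'
#' @return a data frame with 69 rows.
#' @examples
#' tab <- yfh1_thermo_table()
#' select_by_rad(tab, 0.1)   # the 11 buried-core reporters
#' @export
yfh1_thermo_table <- function() {
  path <- system.file("extdata", "yfh1_table1.tsv", package = "foldstab")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  class(df) <- c("rad_table", "data.frame")
  df
}

#' Published consistency classifications of Yfh1 residues
#'
#' The residue sets reported by the original site-specific analysis:
#' `well_behaved` -- the 18 residues whose Tm and Tc differ from the
#' buried-core (RAD < 0.1) reference curve by less than 1.5 K on average;
#' `ill_behaved` -- the 21 residues differing by more than 3 K on average.
#' Labels match `residue_label` in [yfh1_thermo_table()].
#'
#' @return list with character vectors `well_behaved` and `ill_behaved`.
#' @export
yfh1_reported_sets <- function() {
  list(
    well_behaved = c("71 Glu", "75 Glu", "78 Asp", "91 Leu", "101 Asp",
                     "104 Leu", "109 Met", "110 Thr", "119 Tyr", "130 Ile",
                     "132 Leu", "142 Phe", "143 Asp", "152 Leu", "158 Leu",
                     "159 Thr", "160 Asp", "168 Lys"),
    ill_behaved = c("61 Val", "63 Gln", "83 His", "88 Leu", "92 Ser",
                    "95 His", "98 Cys", "99 Ile", "107 Gly", "108 Val",
                    "113 Ile", "120 Val", "127 Asn", "128 Lys", "129 Gln",
                    "136 Leu", "146 Asn", "147 Gly", "154 Asn", "172 Lys",
                    "174 Gln"))
}
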