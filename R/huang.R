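# Published patch-count summary of the Huang ligand-binding benchmark.

#' Patch-count summary of the Huang binding-pocket benchmark
#'
#' Published per-ligand-type summary of the Huang dataset (146 binding
#' pockets of 12 ligand types): number of pockets, number of generated
#' conformers, and the average number of surface patches representing the
#' pockets and the ligand molecules.  Used as a reference for the patch
#' count scales the segmentation should produce, and for consistency checks
#' (pocket and ligand patch counts are strongly correlated because both
#' track molecular size).
#'
#' @return data.frame with columns `ligand`, `n_pockets`, `n_conformers`,
#'   `avg_pocket_patches`, `avg_ligand_patches`.
#' @export
huang_patch_summary <- function() {
  data.frame(
    ligand = c("AND", "BTN", "F6P", "FUC", "GAL", "GUN",
               "MAN", "MMA", "PIM", "PLM", "RTL", "UMP"),
    n_pockets = c(12L, 8L, 10L, 8L, 32L, 11L, 15L, 8L, 5L, 24L, 5L, 8L),
    n_conformers = c(20L, 20L, 20L, 2L, 3L, 1L, 6L, 10L, 2L, 20L, 20L, 20L),
    avg_pocket_patches = c(22.3, 18.6, 19.8, 8.6, 13.9, 14.6,
                           9.3, 13.0, 14.0, 28.3, 31.2, 22.5),
    avg_ligand_patches = c(18.1, 17.7, 16.5, 11.5, 12.7, 10.0,
                           11.5, 13.4, 12.0, 24.1, 25.9, 19.2),
    stringsAsFactors = FALSE)
}
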