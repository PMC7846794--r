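# Built-in marker panels and cell-cycle gene lists (mouse symbols).

#' Default marker panels
#'
#' Named gene sets used throughout the pipeline: endothelial and mesenchymal
#' identity markers, stress-response markers (apoptosis, hypoxia,
#' inflammation), and metabolic pathway sets (glycolysis, TCA cycle, fatty
#' acid signaling, pentose phosphate pathway, glutamine metabolism). All
#' symbols are mouse. The endothelial set of four (`Cdh5`, `Pecam1`, `Vwf`,
#' `Cldn5`) is the default panel for mean z-score kinetics; every set can be
#' overridden by the caller.
#'
#' @return Named list of character vectors of gene symbols.
#' @export
#' @examples
#' names(default_marker_panels())
default_marker_panels <- function() {
  list(
    endothelial  = c("Cdh5", "Pecam1", "Vwf", "Cldn5"),
    endothelial_extended = c("Cdh5", "Pecam1", "Vwf", "Cldn5", "Egfl7",
                             "Emcn", "Tek", "Kdr"),
    mesenchymal  = c("Col1a1", "Col3a1", "Serpine1", "Fn1", "Tagln",
                     "Cnn1", "Acta2", "Pdgfra", "Postn", "Ddr2"),
    endma_gate   = c("Serpine1", "Fn1"),
    immune       = c("Ptprc", "Cd68", "Lyz2", "Itgam", "Fcgr1",
                     "Csf1r", "Adgre1", "Cd52"),
    smc          = c("Myh11", "Pdgfrb", "Notch3", "Des", "Rgs5"),
    stress       = c("Bax", "Trp53", "Hif1a", "Ldha", "Il1b", "Il6", "Tnf"),
    glycolysis   = c("Hk1", "Hk2", "Pfkl", "Pfkm", "Aldoa", "Gapdh",
                     "Pgk1", "Pgam1", "Eno1", "Pkm", "Slc2a1"),
    tca          = c("Cs", "Aco2", "Idh2", "Ogdh", "Sucla2", "Sdha",
                     "Fh1", "Mdh2"),
    fa_signaling = c("Fabp4", "Cd36", "Lpl", "Ppara", "Cpt1a", "Acox1"),
    ppp          = c("G6pdx", "Pgd", "Taldo1", "Tkt"),
    glutamine    = c("Gls", "Glul", "Slc1a5", "Got1")
  )
}

#' Cell-cycle phase gene lists
#'
#' S-phase and G2/M gene sets as mouse orthologs of the canonical human
#' phase markers used by module-score based cell-cycle assignment.
#'
#' @return List with character vectors `s` and `g2m`.
#' @export
default_cell_cycle_genes <- function() {
  list(
    s = c("Mcm5", "Pcna", "Tyms", "Fen1", "Mcm2", "Mcm4", "Rrm1", "Ung",
          "Gins2", "Mcm6", "Cdca7", "Dtl", "Prim1", "Uhrf1", "Hells",
          "Rfc2", "Rpa2", "Nasp", "Rad51ap1", "Gmnn", "Wdr76", "Slbp",
          "Ccne2", "Ubr7", "Pold3", "Msh2", "Atad2", "Rad51", "Rrm2",
          "Cdc45", "Cdc6", "Exo1", "Tipin", "Dscc1", "Blm", "Casp8ap2",
          "Usp1", "Clspn", "Pola1", "Chaf1b", "Brip1", "E2f8"),
    g2m = c("Hmgb2", "Cdk1", "Nusap1", "Ube2c", "Birc5", "Tpx2", "Top2a",
            "Ndc80", "Cks2", "Nuf2", "Cks1b", "Mki67", "Tmpo", "Cenpf",
            "Tacc3", "Smc4", "Ccnb2", "Ckap2l", "Ckap2", "Aurkb", "Bub1",
            "Kif11", "Anp32e", "Tubb4b", "Gtse1", "Kif20b", "Hjurp",
            "Cdca3", "Cdc20", "Ttk", "Kif2c", "Rangap1", "Ncapd2",
            "Dlgap5", "Cdca2", "Cdca8", "Ect2", "Kif23", "Hmmr", "Aurka",
            "Psrc1", "Anln", "Lbr", "Ckap5", "Cenpe", "Ctcf", "Nek2",
            "G2e3", "Gas2l3", "Cbx5", "Cenpa")
  )
}

# Mitochondrial genes included in the simulated universe ("mt-" prefix,
# mouse convention).
mito_gene_symbols <- function() {
  c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp6", "mt-Cytb",
    "mt-Nd4", "mt-Co3")
}
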