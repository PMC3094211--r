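# Assembles the synthetic 56-node cell-cycle + sporulation network fixture and
# its phase-weight table. Run from the package root:
#   Rscript data-raw/yeast56.R
#
# Design notes (see also the methods vignette):
# - cell-cycle engine = the 11-node Boolean core with Cdc20/Cdc14 split out and
#   the FEAR release (Esp1/Spo12/Cdc5 AND -> Cdc14) modeled explicitly;
# - sporulation cascade: Ime1-Ume6-Rim11 AND -> EMG -> Ime2/Ndt80 -> MMG ->
#   SPOR (phenotype AND of EMG, MMG), gated by the PKA axis, the Mig1:Tup1 ->
#   Rpd3 repression and the Sum1:Hst1 middle-gene block;
# - EMG is a self-sustaining latch maintainable by Ndt80 positive feedback, so
#   commitment to sporulation survives a switch back to growth unless the
#   Sum1 block is restored (e.g. by knocking down Ime2);
# - constitutively expressed cofactors are self-activation nodes, transiently
#   expressed ones self-degradation, state-holding ones self-sustaining; the
#   input-free repressors Tup1/Gcn5/Sum1 are self-sustaining so a transient
#   override of them persists (the iPS-style epigenetic flip).

devtools::load_all(".", quiet = TRUE)

proteins_cc <- c("CLN3", "MBF", "SBF", "CLN12", "CLB56", "CLB12", "MCM1SFF",
                 "CDC20", "CDC14", "SWI5", "CDH1", "SIC1", "ESP1", "PDS1",
                 "SPO12", "CDC5")
proteins_spo <- c("IME1", "UME6", "RIM11", "IME2", "NDT80", "SUM1", "HST1",
                  "RIM15", "MSN2", "MSN4", "MIG1", "TUP1", "RPD3", "GCN5",
                  "RME1", "RIM4", "SNF1", "IME4", "CAK1", "SPS1", "SMK1",
                  "AMA1", "SPO13", "SPO11", "DIT1", "MCK1", "SOK2", "MDS3")
ands <- c("AND_FEAR", "AND_IME1C", "AND_MIG1TUP1", "AND_SUM1C", "AND_NDT80C")
groups <- c("EMG", "MMG")

ids <- c(proteins_cc, proteins_spo, ands, groups, "PKA", "SPOR",
         "CELL_SIZE", "GROWTH", "SPOR_COND")
stopifnot(length(ids) == 56)

kind <- c(rep("protein", 44), rep("logic_and", 5), rep("gene_group", 2),
          "pathway", "phenotype", rep("signal", 3))
deg <- c("CLN3", "CLN12", "CLB56", "CLB12", "SWI5", "CDC20", "MCM1SFF",
         "CDC5", "SPO12", "CDC14", "IME1", "IME2", "NDT80", "RPD3", "RME1",
         "SOK2", "MCK1", "IME4", "RIM4", "SPO11", "SPO13", "DIT1", "SPS1",
         "SMK1", "AMA1", "PKA", "MMG", "EMG", "GCN5")
act <- c("ESP1", "PDS1", "RIM11", "HST1", "MDS3", "CAK1")
self_mode <- ifelse(ids %in% deg, "degradation",
                    ifelse(ids %in% act, "activation", "sustaining"))
perturbable <- ids %in% c(proteins_cc, proteins_spo) & !ids %in% c("MBF", "MCM1SFF")
stopifnot(sum(perturbable) == 42)

E <- rbind(
  ## cell-cycle engine (cell-size checkpoint through mitotic exit)
  c("CELL_SIZE", "CLN3", 1, "core"),
  c("CLN3", "MBF", 1, "core"), c("CLN3", "SBF", 1, "core"),
  c("SBF", "CLN12", 1, "core"),
  c("CLN12", "SIC1", -1, "core"), c("CLN12", "CDH1", -1, "core"),
  c("MBF", "CLB56", 1, "core"),
  c("CLB56", "MCM1SFF", 1, "core"), c("CLB56", "CLB12", 1, "core"),
  c("CLB56", "SIC1", -1, "core"), c("CLB56", "CDH1", -1, "core"),
  c("CLB12", "MCM1SFF", 1, "core"), c("CLB12", "CDC20", 1, "core"),
  c("CLB12", "SIC1", -1, "core"), c("CLB12", "SWI5", -1, "core"),
  c("CLB12", "CDH1", -1, "core"), c("CLB12", "MBF", -1, "core"),
  c("CLB12", "SBF", -1, "core"),
  c("MCM1SFF", "CLB12", 1, "core"), c("MCM1SFF", "CDC20", 1, "core"),
  c("MCM1SFF", "SWI5", 1, "core"),
  c("MCM1SFF", "CDC5", 1, "synthetic"), c("MCM1SFF", "SPO12", 1, "synthetic"),
  c("CDC20", "PDS1", -1, "synthetic"), c("CDC20", "CLB56", -1, "core"),
  c("CDC20", "CLB12", -1, "core"),
  c("PDS1", "ESP1", -1, "synthetic"),
  c("ESP1", "AND_FEAR", 1, "synthetic"), c("SPO12", "AND_FEAR", 1, "synthetic"),
  c("CDC5", "AND_FEAR", 1, "synthetic"),
  c("AND_FEAR", "CDC14", 1, "synthetic"),
  c("CDC14", "SWI5", 1, "core"), c("CDC14", "CDH1", 1, "core"),
  c("CDC14", "SIC1", 1, "core"),
  c("SWI5", "SIC1", 1, "core"),
  c("SIC1", "CLB56", -1, "core"), c("SIC1", "CLB12", -1, "core"),
  c("CDH1", "CLB12", -1, "core"),
  ## nutrient signals and the PKA axis
  c("GROWTH", "PKA", 1, "main_text"), c("SPOR_COND", "PKA", -1, "synthetic"),
  c("GROWTH", "MIG1", 1, "main_text"), c("GROWTH", "IME1", -1, "main_text"),
  c("GROWTH", "SNF1", -1, "synthetic"), c("SPOR_COND", "SNF1", 1, "synthetic"),
  c("GROWTH", "RME1", 1, "synthetic"), c("SPOR_COND", "TUP1", -1, "synthetic"),
  c("SPOR_COND", "IME1", 1, "main_text"), c("SPOR_COND", "IME4", 1, "synthetic"),
  c("SPOR_COND", "MCK1", 1, "synthetic"),
  c("PKA", "RIM15", -1, "main_text"), c("PKA", "MSN2", -1, "main_text"),
  c("PKA", "MSN4", -1, "synthetic"), c("PKA", "RIM11", -1, "synthetic"),
  c("PKA", "SOK2", 1, "synthetic"),
  ## Ime1 integration
  c("RIM15", "IME1", 1, "synthetic"), c("MSN2", "IME1", 1, "synthetic"),
  c("MSN4", "IME1", 1, "main_text"),
  c("SNF1", "MIG1", -1, "synthetic"),
  c("MIG1", "IME1", -1, "synthetic"), c("MIG1", "IME4", -1, "synthetic"),
  c("RPD3", "IME1", -1, "synthetic"), c("SOK2", "IME1", -1, "synthetic"),
  c("RME1", "IME1", -1, "main_text"),
  c("IME1", "RME1", -1, "synthetic"),
  c("MCK1", "IME1", 1, "synthetic"), c("IME4", "IME1", 1, "synthetic"),
  c("MDS3", "IME1", 1, "synthetic"), c("CLN12", "IME1", -1, "synthetic"),
  ## Tup1-Mig1 complex activates Rpd3
  c("MIG1", "AND_MIG1TUP1", 1, "main_text"),
  c("TUP1", "AND_MIG1TUP1", 1, "main_text"),
  c("AND_MIG1TUP1", "RPD3", 1, "main_text"),
  c("MIG1", "RPD3", 1, "synthetic"),
  ## early meiotic genes: Ime1-complex ignition, Ndt80 feedback latch,
  ## Gcn5 acetylation push against the Rpd3/Tup1 repression
  c("IME1", "AND_IME1C", 1, "main_text"), c("UME6", "AND_IME1C", 1, "main_text"),
  c("RIM11", "AND_IME1C", 1, "main_text"),
  c("AND_IME1C", "EMG", 1, "main_text"),
  c("NDT80", "EMG", 1, "synthetic"), c("IME2", "EMG", 1, "synthetic"),
  c("GCN5", "EMG", 1, "synthetic"),
  c("RPD3", "EMG", -1, "main_text"), c("TUP1", "EMG", -1, "synthetic"),
  c("EMG", "IME2", 1, "main_text"), c("EMG", "NDT80", 1, "main_text"),
  c("EMG", "SPO11", 1, "synthetic"), c("EMG", "SPO13", 1, "synthetic"),
  c("EMG", "RIM4", 1, "synthetic"),
  ## Ndt80 / Sum1 switch and middle meiotic genes
  c("IME2", "SUM1", -1, "main_text"),
  c("SUM1", "AND_SUM1C", 1, "synthetic"), c("HST1", "AND_SUM1C", 1, "synthetic"),
  c("AND_SUM1C", "NDT80", -1, "main_text"), c("AND_SUM1C", "IME2", -1, "synthetic"),
  c("TUP1", "NDT80", -1, "synthetic"),
  c("AND_SUM1C", "MMG", -1, "main_text"),
  c("NDT80", "IME2", 1, "main_text"), c("IME2", "NDT80", 1, "synthetic"),
  c("NDT80", "IME1", 1, "main_text"),
  c("NDT80", "AND_NDT80C", 1, "main_text"), c("IME2", "AND_NDT80C", 1, "synthetic"),
  c("AND_NDT80C", "MMG", 1, "main_text"),
  c("MMG", "SPS1", 1, "synthetic"), c("MMG", "SMK1", 1, "synthetic"),
  c("CAK1", "SMK1", 1, "synthetic"), c("SMK1", "DIT1", 1, "synthetic"),
  c("MMG", "AMA1", 1, "synthetic"), c("AMA1", "CLB12", -1, "synthetic"),
  ## sporulation phenotype: conjunction of EMG and MMG
  c("EMG", "SPOR", 1, "main_text"), c("MMG", "SPOR", 1, "main_text"))

nodes <- data.frame(id = ids, label = ids, kind = kind, self_mode = self_mode,
                    perturbable = perturbable, stringsAsFactors = FALSE)
edges <- data.frame(source = E[, 1], target = E[, 2], sign = as.integer(E[, 3]),
                    provenance = E[, 4], stringsAsFactors = FALSE)
net <- regnet(nodes, edges,
              signals = list(growth = "GROWTH", sporulation = "SPOR_COND",
                             cell_size = "CELL_SIZE", spor_node = "SPOR"),
              name = "yeast56_synthetic")
write_network(net, "inst/extdata/yeast56_synthetic.json", "json")
cat("wrote network:", nrow(net$nodes), "nodes,", nrow(net$edges), "edges\n")

## --- derived phase weights -------------------------------------------------
mk <- identify_cyclic_markers(net, condition(net, "growth"),
                              n_init = 20000L, seed = 42L)
cat("markers (", length(mk$markers), "):", paste(mk$markers, collapse = " "), "\n")
cat("largest attractor basin:", mk$attractor$basin_count, "/ 20000\n")
tr <- mk$trajectory
lab <- label_cc_phases(tr$states, cdc20 = "CDC20")
cat("trajectory phases:", paste(rle(lab)$values, collapse = " > "), "\n")
pw <- derive_phase_weights(tr$states[-1, , drop = FALSE], lab[-1], mk$markers)
ok <- vapply(2:nrow(tr$states), function(i)
  assign_phase(tr$states[i, ], pw)$phase == lab[i], logical(1))
cat("phase self-assignment correct:", sum(ok), "/", length(ok), "\n")
w <- data.frame(node = rownames(pw$w), pw$w, check.names = FALSE)
utils::write.table(w, "inst/extdata/yeast56_phase_weights_synthetic.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

## quick dynamic audit under the three conditions
scheme <- classification_scheme(net, mk$markers, mk$reference)
for (cname in c("growth", "sporulation", "none")) {
  sr <- sample_attractors(net, condition(net, cname), seed = 7L,
                          batch = 5000L, cap = 40000L, scheme = scheme)
  n_cc <- sum(vapply(sr$attractors, function(a)
    identical(a$class, "cell_cycle"), logical(1)))
  cat(cname, ": n=", sr$n_sampled, " cc-attractors:", n_cc, " fractions:",
      paste(names(sr$fractions), round(sr$fractions, 3), collapse = "  "), "\n")
}

## wild-type viability
wt <- check_viability(net, NULL, scheme, pw, start_state = mk$attractor$states[1, ])
cat("wild-type viable:", wt$viable, "|",
    paste(wt$phase_sequence, collapse = " > "), "\n")
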