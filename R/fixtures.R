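#' The 11-node budding-yeast cell-cycle network
#'
#' The classic synchronous Boolean model of the yeast cell-cycle engine:
#' eleven regulatory proteins (Cln3, MBF, SBF, Cln1/2, Cdh1, Swi5,
#' Cdc20/Cdc14, Clb5/6, Sic1, Clb1/2, Mcm1/SFF) plus a cell-size checkpoint
#' signal that pulses Cln3 to launch a division. Nodes with active
#' degradation are in self-degradation mode; the rest self-sustain. Its
#' dominant fixed point is the stationary G1 state (Cdh1 and Sic1 on,
#' everything else off).
#'
#' @return a `regnet` with 12 nodes (11 proteins + 1 signal).
#' @export
yeast_cc11 <- function() {
  deg <- c("CLN3", "CLN12", "SWI5", "CDC2014", "MCM1SFF")
  ids <- c("CELL_SIZE", "CLN3", "MBF", "SBF", "CLN12", "CDH1", "SWI5",
           "CDC2014", "CLB56", "SIC1", "CLB12", "MCM1SFF")
  nodes <- data.frame(
    id = ids, label = ids,
    kind = c("signal", rep("protein", 11)),
    self_mode = ifelse(ids %in% deg, "degradation", "sustaining"),
    stringsAsFactors = FALSE)
  E <- rbind(
    c("CELL_SIZE", "CLN3", 1),
    c("CLN3", "MBF", 1), c("CLN3", "SBF", 1),
    c("SBF", "CLN12", 1),
    c("CLN12", "SIC1", -1), c("CLN12", "CDH1", -1),
    c("MBF", "CLB56", 1),
    c("CLB56", "MCM1SFF", 1), c("CLB56", "CLB12", 1),
    c("CLB56", "SIC1", -1), c("CLB56", "CDH1", -1),
    c("CLB12", "MCM1SFF", 1), c("CLB12", "CDC2014", 1),
    c("CLB12", "SIC1", -1), c("CLB12", "SWI5", -1), c("CLB12", "CDH1", -1),
    c("CLB12", "MBF", -1), c("CLB12", "SBF", -1),
    c("MCM1SFF", "CLB12", 1), c("MCM1SFF", "CDC2014", 1), c("MCM1SFF", "SWI5", 1),
    c("CDC2014", "SWI5", 1), c("CDC2014", "CDH1", 1), c("CDC2014", "SIC1", 1),
    c("CDC2014", "CLB12", -1), c("CDC2014", "CLB56", -1),
    c("SWI5", "SIC1", 1),
    c("SIC1", "CLB56", -1), c("SIC1", "CLB12", -1),
    c("CDH1", "CLB12", -1))
  edges <- data.frame(source = E[, 1], target = E[, 2],
                      sign = as.integer(E[, 3]), stringsAsFactors = FALSE)
  regnet(nodes, edges, signals = list(cell_size = "CELL_SIZE"),
         name = "yeast_cc11")
}

#' The packaged 56-node cell-cycle plus sporulation network (synthetic)
#'
#' A synthetic reconstruction of a 56-node budding-yeast network coupling the
#' cell-cycle engine to the sporulation program: 44 proteins/complexes, 5
#' logical AND nodes, the EMG/MMG early- and middle-meiotic gene groups, the
#' cAMP/PKA pathway node, the SPOR sporulation phenotype (an AND of EMG and
#' MMG) and three signal nodes (cell size, growth condition, sporulation
#' condition). The edge list was assembled from published interaction
#' descriptions of the two programs; it is a stand-in curation, not a
#' transcription of any single published supplementary table, and the edge
#' `provenance` column records the support class of each interaction.
#'
#' @return a `regnet` with 56 nodes.
#' @export
yeast56 <- function() {
  path <- system.file("extdata", "yeast56_synthetic.json", package = "refate")
  if (path == "") stop("packaged network fixture not found")
  read_network(path, "json")
}

#' Phase weights for the packaged 56-node network (synthetic)
#'
#' Weights derived with [derive_phase_weights()] from the network's own
#' excited (START) trajectory under growth condition, with phase labels
#' assigned from cyclin/APC activity; shipped as a TSV so the viability
#' pipeline runs out of the box.
#'
#' @return a [phase_weights()] object.
#' @export
yeast56_weights <- function() {
  path <- system.file("extdata", "yeast56_phase_weights_synthetic.tsv",
                      package = "refate")
  if (path == "") stop("packaged weights fixture not found")
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(w[, -1])
  rownames(m) <- w[[1]]
  colnames(m) <- sub("^stationary\\.G1$", "stationary_G1", colnames(m))
  phase_weights(m, CC_PHASES)
}

#' Label the states of a cell-cycle trajectory by phase
#'
#' Rule-based phase labels from cyclin and checkpoint activity: START while
#' Cln3 is on; S once Clb5/6 rises; G2 with Clb1/2 on before the APC
#' (Cdc20) fires; M while Clb1/2 and Cdc20 are on; the final fixed point is
#' stationary G1; everything else (cyclins off) is G1. Used to bootstrap
#' phase weights for networks that include the cell-cycle core nodes.
#'
#' @param states trajectory state matrix with named columns.
#' @param cln3,clb56,clb12,cdc20 column names of the phase-indicator nodes.
#' @param cell_size optional column name of the size-checkpoint signal; a
#'   state with the signal on is part of the START excitation.
#' @return character vector of labels from [phase_weights()]'s phase set.
#' @export
label_cc_phases <- function(states, cln3 = "CLN3", clb56 = "CLB56",
                            clb12 = "CLB12", cdc20 = "CDC2014",
                            cell_size = "CELL_SIZE") {
  n <- nrow(states)
  has_cs <- !is.null(cell_size) && cell_size %in% colnames(states)
  lab <- character(n)
  for (i in seq_len(n)) {
    s <- states[i, ]
    lab[i] <- if (i == n) "stationary_G1"
      else if (s[cln3] == 1 || (has_cs && s[cell_size] == 1)) "START"
      else if (s[clb12] == 1 && s[cdc20] == 1) "M"
      else if (s[clb12] == 1) "G2"
      else if (s[clb56] == 1) "S"
      else "G1"
  }
  lab
}
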