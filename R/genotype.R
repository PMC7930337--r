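#' Motorneuron classes of the repeating ventral nerve cord unit
#'
#' The seven classes, in the fixed order used everywhere in the package:
#' AS, DA, DB, DD, VD, VA, VB. AS-, A- and B-class neurons are cholinergic
#' (excitatory neuromuscular junctions); D-class neurons are GABAergic
#' (inhibitory neuromuscular junctions). Classes AS, DA, DB, DD innervate
#' dorsal muscles; VD, VA, VB innervate ventral muscles.
#'
#' @return character vector of the seven class labels.
#' @export
neuron_classes <- function() c("AS", "DA", "DB", "DD", "VD", "VA", "VB")

# fixed by neurotransmitter identity, not evolved
nmj_sign_for <- function(classes) {
  ifelse(classes %in% c("DD", "VD"), -1, 1)
}

dorsal_classes <- function() c("AS", "DA", "DB", "DD")
ventral_classes <- function() c("VD", "VA", "VB")

# the nine evolved intraunit chemical synapses, as (pre, post) pairs
intraunit_chem_pairs <- function() {
  list(c("AS", "DA"), c("AS", "VD"), c("DA", "DB"), c("DB", "AS"),
       c("VD", "VA"), c("VD", "VB"), c("DA", "DD"), c("VB", "DD"),
       c("VA", "DD"))
}

chem_pair_name <- function(p) paste0(p[1], "_to_", p[2])

#' Genotype layout
#'
#' The 44-slot layout of the normalized genotype: 28 class parameters
#' (7 biases, 7 time constants, 7 self-connection weights, 7 neuromuscular
#' junction magnitudes), 15 connection parameters (9 intraunit chemical
#' weights, the VD-DD intraunit gap junction, 2 interunit chemical weights
#' DB->DD+1 and VA+1->DD, and 3 interunit gap junctions DA-AS+1, VB-DB+1,
#' AS-VA+1), and the anterior-posterior muscle gain F. Each slot is a real in
#' \[-1, 1\] mapped linearly onto its range from the configuration file; gap
#' junction and NMJ slots map onto non-negative ranges (NMJ signs are fixed by
#' class).
#'
#' @return data.frame with columns `slot` (name), `kind` (range class used to
#'   decode) and `index` (1..44).
#' @export
genotype_layout <- function() {
  cl <- neuron_classes()
  chems <- vapply(intraunit_chem_pairs(), chem_pair_name, character(1))
  slots <- c(paste0("bias_", cl), paste0("tau_", cl), paste0("wself_", cl),
             paste0("nmj_", cl), chems, "g_VD_DD", "DB_to_DDp1", "VAp1_to_DD",
             "g_DA_ASp1", "g_VB_DBp1", "g_AS_VAp1", "gain_F")
  kind <- c(rep("bias", 7), rep("tau", 7), rep("w_self", 7), rep("nmj", 7),
            rep("chem", 9), "gap", "chem", "chem", "gap", "gap", "gap",
            "gain_F")
  data.frame(slot = slots, kind = kind, index = seq_along(slots),
             stringsAsFactors = FALSE)
}

#' Construct a genotype
#'
#' @param values numeric vector of length 44 with entries in \[-1, 1\].
#' @return a named `wcpg_genotype` vector.
#' @export
genotype <- function(values) {
  layout <- genotype_layout()
  if (length(values) != nrow(layout))
    stop("genotype must have exactly ", nrow(layout), " values, got ",
         length(values))
  if (any(!is.finite(values))) stop("genotype values must be finite")
  if (any(abs(values) > 1 + 1e-9))
    warning("genotype values outside the normalized range [-1, 1]")
  values <- as.numeric(values)
  names(values) <- layout$slot
  class(values) <- "wcpg_genotype"
  values
}

#' @export
print.wcpg_genotype <- function(x, ...) {
  cat("wormCPG genotype (44 normalized parameters)\n")
  print(round(unclass(x), 4))
  invisible(x)
}

range_table <- function(config) {
  layout <- genotype_layout()
  rg <- config$ranges
  missing <- setdiff(unique(layout$kind), names(rg))
  if (length(missing))
    stop("range table missing slot kind(s): ", paste(missing, collapse = ", "))
  lo <- vapply(layout$kind, function(k) rg[[k]][1], numeric(1),
               USE.NAMES = FALSE)
  hi <- vapply(layout$kind, function(k) rg[[k]][2], numeric(1),
               USE.NAMES = FALSE)
  rt <- cbind(lo = lo, hi = hi)
  rownames(rt) <- layout$slot
  rt
}

#' Decode a genotype into model parameters
#'
#' Maps each normalized slot linearly from \[-1, 1\] onto its configured
#' range. NMJ slots decode to magnitudes only; the sign (excitatory for
#' AS/DA/DB/VA/VB, inhibitory for DD/VD) is applied from the class identity.
#' The decode is deterministic and inverted exactly by [encode_genotype()].
#'
#' @param g a [genotype()] or plain numeric vector of length 44.
#' @param config a [wcpg_config()].
#' @return a `wcpg_params` list with `class_params` (data.frame: class, bias,
#'   tau, w_self, nmj_q, nmj_sign), `connectome` (named weights:
#'   `chem_intra`, `gap_intra`, `chem_inter`, `gap_inter`) and `gain_F`.
#' @export
decode_genotype <- function(g, config = wcpg_config()) {
  if (!inherits(g, "wcpg_genotype")) g <- genotype(g)
  rt <- range_table(config)
  real <- rt[, "lo"] + (unclass(g) + 1) / 2 * (rt[, "hi"] - rt[, "lo"])
  cl <- neuron_classes()
  class_params <- data.frame(
    class = cl,
    bias = unname(real[paste0("bias_", cl)]),
    tau = unname(real[paste0("tau_", cl)]),
    w_self = unname(real[paste0("wself_", cl)]),
    nmj_q = unname(real[paste0("nmj_", cl)]),
    nmj_sign = nmj_sign_for(cl),
    stringsAsFactors = FALSE)
  chems <- vapply(intraunit_chem_pairs(), chem_pair_name, character(1))
  out <- list(
    class_params = class_params,
    connectome = list(
      chem_intra = real[chems],
      gap_intra = c(g_VD_DD = unname(real["g_VD_DD"])),
      chem_inter = real[c("DB_to_DDp1", "VAp1_to_DD")],
      gap_inter = real[c("g_DA_ASp1", "g_VB_DBp1", "g_AS_VAp1")]),
    gain_F = unname(real["gain_F"]))
  class(out) <- c("wcpg_params", "list")
  out
}

#' Re-encode model parameters into a normalized genotype
#'
#' Exact inverse of [decode_genotype()] on the fixed layout.
#'
#' @param params a `wcpg_params` list.
#' @param config a [wcpg_config()].
#' @return a [genotype()].
#' @export
encode_genotype <- function(params, config = wcpg_config()) {
  cl <- neuron_classes()
  cp <- params$class_params
  cp <- cp[match(cl, cp$class), ]
  con <- params$connectome
  real <- c(cp$bias, cp$tau, cp$w_self, cp$nmj_q,
            unname(con$chem_intra), unname(con$gap_intra),
            unname(con$chem_inter), unname(con$gap_inter), params$gain_F)
  rt <- range_table(config)
  norm <- 2 * (real - rt[, "lo"]) / (rt[, "hi"] - rt[, "lo"]) - 1
  genotype(norm)
}

#' @export
print.wcpg_params <- function(x, ...) {
  cat("wormCPG decoded parameters\n")
  print(x$class_params, row.names = FALSE)
  cat("intraunit chemical weights:\n")
  print(round(x$connectome$chem_intra, 3))
  cat(sprintf("VD-DD gap: %.3f\n", x$connectome$gap_intra))
  cat("interunit chemical:\n")
  print(round(x$connectome$chem_inter, 3))
  cat("interunit gap junctions:\n")
  print(round(x$connectome$gap_inter, 3))
  cat(sprintf("anterior-posterior muscle gain F: %.3f\n", x$gain_F))
  invisible(x)
}
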