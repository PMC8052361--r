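#' Map a STRIDE secondary-structure code to a structural class
#'
#' STRIDE codes H, G and I (alpha-, 3-10- and pi-helix) map to `HELIX`; B, b
#' and E (isolated bridge and extended strand) map to `STRAND`; everything
#' else maps to `OTHER`. Atoms belonging to DNA/RNA are `NUCLEIC` regardless
#' of any code. Unknown codes fall through to `OTHER` (with a warning-level
#' message, not an error).
#'
#' @param stride_code Character vector of one-letter STRIDE codes.
#' @param is_nucleic Logical vector (recycled): residue belongs to DNA/RNA.
#' @return Character vector of class labels (see [class_labels()]).
#' @export
stride_to_class <- function(stride_code, is_nucleic = FALSE) {
  n <- max(length(stride_code), length(is_nucleic))
  code <- rep_len(as.character(stride_code), n)
  nuc <- rep_len(as.logical(is_nucleic), n)
  known <- c("H", "G", "I", "B", "b", "E", "T", "C", " ", "")
  unknown <- !(code %in% known) & !nuc
  if (any(unknown))
    message(sprintf("stride_to_class: %d unknown STRIDE code(s) treated as OTHER",
                    sum(unknown)))
  out <- ifelse(code %in% c("H", "G", "I"), "HELIX",
                ifelse(code %in% c("B", "b", "E"), "STRAND", "OTHER"))
  out[nuc] <- "NUCLEIC"
  out
}

#' Parse a STRIDE report into a per-residue label table
#'
#' Consumes the ASG records of a STRIDE output file (STRIDE itself is never
#' executed). Columns used: residue name, chain, residue number, and the
#' one-letter secondary-structure code.
#'
#' @param path Path to a STRIDE report.
#' @param nucleic_chains Chains to force to `NUCLEIC` (STRIDE only annotates
#'   protein).
#' @return Data frame with `chain_id`, `residue_index`, `label`.
#' @export
read_stride <- function(path, nucleic_chains = character(0)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  asg <- lines[startsWith(lines, "ASG")]
  if (length(asg) == 0L) stop("no ASG records found in STRIDE report")
  # fixed-ish columns: ASG  RES  CHAIN  PDBNUM  ORDNUM  CODE  ...
  parts <- strsplit(trimws(asg), "\\s+")
  chain <- vapply(parts, `[`, character(1), 3L)
  resno <- as.integer(vapply(parts, `[`, character(1), 4L))
  code <- vapply(parts, `[`, character(1), 6L)
  nuc <- chain %in% nucleic_chains
  data.frame(chain_id = chain, residue_index = resno,
             label = stride_to_class(code, nuc),
             stringsAsFactors = FALSE)
}
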