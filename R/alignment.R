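#' Construct an aligned sequence set
#'
#' The substrate of all genetic computation in the package: a tibble with one
#' row per sequence and columns `id` and `seq`. Sequences are stored
#' uppercase, must be of identical length and may contain the four bases,
#' IUPAC ambiguity codes, `N` and the gap character `-`.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of aligned nucleotide sequences.
#' @return A tibble of class `skt_alignment` with columns `id` and `seq`.
#' @examples
#' aln <- alignment(c("a", "b"), c("ACGTACGT", "ACGTACGA"))
#' n_sites(aln)
#' @export
alignment <- function(id, seq) {
  id <- trimws(as.character(id))
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    abort_input("`id` and `seq` must have the same length")
  }
  if (length(id) == 0) {
    abort_input("alignment contains no sequences")
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    abort_input(paste0("duplicate sequence identifier(s): ",
                       paste(dup, collapse = ", ")))
  }
  lens <- nchar(seq)
  if (length(unique(lens)) != 1) {
    bad <- id[lens != lens[[1]]][[1]]
    abort_alignment(paste0(
      "sequences are not aligned: '", bad, "' has length ",
      lens[lens != lens[[1]]][[1]], " but '", id[[1]], "' has length ", lens[[1]]
    ))
  }
  if (lens[[1]] < 1) {
    abort_input("aligned sequences must have length >= 1")
  }
  stripped <- gsub(paste0("[", paste(IUPAC_OK, collapse = ""), "]"), "", seq)
  if (any(nchar(stripped) > 0)) {
    bad <- id[nchar(stripped) > 0][[1]]
    ch <- substr(stripped[nchar(stripped) > 0][[1]], 1, 1)
    abort_input(paste0("record '", bad, "' contains invalid character '", ch, "'"))
  }
  out <- tibble::tibble(id = id, seq = seq)
  class(out) <- c("skt_alignment", class(out))
  out
}

#' Number of sites (columns) in an alignment
#'
#' @param aln An `skt_alignment`.
#' @return Integer site count.
#' @export
n_sites <- function(aln) {
  nchar(aln$seq[[1]])
}

# alignment as a character matrix (rows = sequences)
seq_matrix <- function(aln) {
  n <- nrow(aln)
  L <- n_sites(aln)
  matrix(unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE,
         dimnames = list(aln$id, NULL))
}

#' Read an aligned FASTA file
#'
#' Accepts wrapped or unwrapped multi-record FASTA. Records are uppercased;
#' the alignment length is taken from the first record and every record must
#' match it.
#'
#' @param path Path to a FASTA file.
#' @param format Input format; only `"fasta"` is supported.
#' @return An [alignment()] tibble.
#' @export
read_alignment <- function(path, format = "fasta") {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) {
    abort_input(paste0("file not found: ", path))
  }
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort_input(paste0("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  )
  if (length(x) == 0) {
    abort_input(paste0("FASTA file '", path, "' contains no records"))
  }
  alignment(names(x), as.character(x))
}

#' Write an alignment to FASTA
#'
#' @param aln An `skt_alignment` (or any tibble with `id` and `seq`).
#' @param path Output path.
#' @param width Line-wrap width in characters (default 70).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", aln$id[[i]]), con)
    s <- aln$seq[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# supported translation tables -> NCBI genetic-code ids
GENETIC_CODES <- c(
  "standard" = "1",
  "vertebrate mitochondrial" = "2"
)

#' Check a reading frame for premature stop codons
#'
#' Protein-coding mitochondrial fragments (such as ND2/ND4) should translate
#' without internal stops; any stop codon flags a likely alignment or
#' sequencing problem (or a numt). Codons containing a gap or ambiguity code
#' are skipped. Under the vertebrate mitochondrial code, AGA and AGG are
#' stops in addition to TAA and TAG.
#'
#' @param aln An `skt_alignment`.
#' @param frame Reading-frame offset in `{0, 1, 2}`: number of columns to
#'   skip before the first codon.
#' @param code Translation-table name: `"vertebrate mitochondrial"` (default)
#'   or `"standard"`.
#' @return A tibble with columns `id` and `codon` (1-based codon index),
#'   one row per stop codon found; zero rows means the alignment passes.
#' @export
check_reading_frame <- function(aln, frame = 0,
                                code = "vertebrate mitochondrial") {
  if (!frame %in% c(0, 1, 2)) {
    abort_config("`frame` must be 0, 1 or 2")
  }
  code <- tolower(code)
  if (!code %in% names(GENETIC_CODES)) {
    abort_config(paste0("unknown genetic code '", code, "'; supported: ",
                        paste(names(GENETIC_CODES), collapse = ", ")))
  }
  gc_tab <- Biostrings::getGeneticCode(GENETIC_CODES[[code]])
  stops <- names(gc_tab)[gc_tab == "*"]
  out <- purrr::map_dfr(seq_len(nrow(aln)), function(i) {
    s <- substring(aln$seq[[i]], frame + 1)
    n_codon <- nchar(s) %/% 3
    if (n_codon == 0) {
      return(tibble::tibble(id = character(), codon = integer()))
    }
    starts <- 3 * (seq_len(n_codon) - 1) + 1
    codons <- substring(s, starts, starts + 2)
    callable <- !grepl("[^ACGT]", codons)
    hit <- which(callable & codons %in% stops)
    tibble::tibble(id = rep(aln$id[[i]], length(hit)), codon = hit)
  })
  out
}

#' Collapse aligned sequences to haplotypes
#'
#' Individuals sharing an identical aligned sequence share a haplotype.
#' Under `strict`, two sequences share a haplotype iff they are
#' character-identical; under `ignore-ambiguous-sites`, columns containing
#' any gap, `N` or IUPAC ambiguity code in any sequence are excluded before
#' comparison. Labels are assigned in order of first appearance with a
#' zero-padded numeric suffix, so the result is deterministic for a fixed
#' input order.
#'
#' @param aln An `skt_alignment`.
#' @param label_prefix Prefix for haplotype labels (e.g. `"MAF"`).
#' @param ambiguity_policy `"strict"` (default) or `"ignore-ambiguous-sites"`.
#' @return A tibble of class `skt_haplotypes` with columns `label`, `seq`
#'   (the full sequence of the first member) and `members` (list column of
#'   identifiers).
#' @examples
#' aln <- alignment(c("x", "y", "z"), c("ACGT", "ACGT", "ACGA"))
#' collapse_haplotypes(aln, "H")
#' @export
collapse_haplotypes <- function(aln, label_prefix = "H",
                                ambiguity_policy = c("strict",
                                                     "ignore-ambiguous-sites")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  if (nrow(aln) == 0) {
    abort_input("cannot collapse an empty alignment")
  }
  if (ambiguity_policy == "strict") {
    keys <- aln$seq
  } else {
    m <- seq_matrix(aln)
    keep <- !apply(m, 2, function(col) any(!col %in% DNA_BASES))
    keys <- apply(m[, keep, drop = FALSE], 1, paste0, collapse = "")
    if (!length(keys)) keys <- rep("", nrow(aln))
  }
  grp <- match(keys, unique(keys))
  width <- max(2L, nchar(as.character(max(grp))))
  out <- tibble::tibble(
    label = sprintf("%s%0*d", label_prefix, width, sort(unique(grp))),
    seq = aln$seq[match(sort(unique(grp)), grp)],
    members = unname(split(aln$id, grp))
  )
  class(out) <- c("skt_haplotypes", class(out))
  attr(out, "label_prefix") <- label_prefix
  attr(out, "ambiguity_policy") <- ambiguity_policy
  out
}

# haplotype table viewed as an alignment of its representative sequences
haplotype_alignment <- function(haps) {
  alignment(haps$label, haps$seq)
}

# accept either an alignment or a haplotype table where labelled sequences
# are needed
as_labelled_alignment <- function(x) {
  if (inherits(x, "skt_haplotypes")) {
    haplotype_alignment(x)
  } else if (inherits(x, "skt_alignment")) {
    x
  } else if (is.data.frame(x) && all(c("label", "seq") %in% names(x))) {
    alignment(x$label, x$seq)
  } else if (is.data.frame(x) && all(c("id", "seq") %in% names(x))) {
    alignment(x$id, x$seq)
  } else {
    abort_input("expected an alignment or haplotype table")
  }
}
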