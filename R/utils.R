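# Small shared helpers: base complement tables, trapezoidal quadrature,
# genome loading. Internal only.

.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' @noRd
comp_base <- function(b) unname(COMPLEMENT[b])

# Complement an ordered substitution code, e.g. "TC" -> "AG". The same genomic
# event seen from the opposite strand profile.
#' @noRd
comp_pair <- function(code) {
  vapply(strsplit(code, ""), function(p) {
    paste0(COMPLEMENT[p[1]], COMPLEMENT[p[2]])
  }, character(1))
}

# All 12 ordered substitution codes (ref != read).
#' @noRd
all_subst_codes <- function() {
  g <- expand.grid(ref = BASES, read = BASES, stringsAsFactors = FALSE)
  g <- g[g$ref != g$read, ]
  paste0(g$ref, g$read)
}

# Trapezoidal rule on an ordered grid.
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Load a reference genome
#'
#' Accepts a \code{DNAStringSet}, a named character vector of sequences, or a
#' path to a FASTA file and returns a \code{DNAStringSet}.
#'
#' @param genome \code{DNAStringSet}, named character vector, or FASTA path.
#' @return A \code{DNAStringSet}.
#' @export
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  stop("cannot interpret `genome`: supply a DNAStringSet, a named character ",
       "vector or a FASTA path")
}

# Per-chromosome character vector of (uppercased) bases, cached per call site.
#' @noRd
chrom_chars <- function(genome, chrom) {
  strsplit(toupper(as.character(genome[[chrom]])), "")[[1]]
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
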