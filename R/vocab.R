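#' Combined amino-acid/codon token vocabulary
#'
#' Builds the fixed token inventory used throughout the package: one combined
#' `aa_codon` token per codon (61 sense codons plus the 3 stop codons, the
#' stops grouped under a dedicated `stop` symbol), 20 masked amino-acid tokens
#' (`a_unk` ... `y_unk`) standing for residues whose codon is not yet chosen,
#' and 5 special tokens (`unk`, `cls`, `sep`, `pad`, `mask`). Each token
#' carries its GC fraction (number of G/C letters among the codon's three
#' nucleotides divided by 3; 0 for non-codon tokens), and sense codons are
#' grouped into synonymous families keyed by amino-acid letter (`*` for the
#' stop family).
#'
#' @return An object of class `codon_vocab`: a list with elements
#'   `tokens` (ordered character vector), `gc_fraction` (named numeric,
#'   token -> GC fraction in `[0, 1]`), `families` (named list, amino-acid
#'   letter -> character vector of codon tokens in lexicographic codon order),
#'   `token_index` (named integer, token -> 1-based id), `codon_of` and
#'   `aa_of` (named character, codon-bearing token -> codon / amino-acid
#'   letter).
#' @examples
#' v <- build_vocabulary()
#' v$families[["M"]]                 # "m_atg"
#' v$gc_fraction[["g_ggc"]]          # 1
#' @export
build_vocabulary <- function() {
  code <- Biostrings::GENETIC_CODE  # codon -> amino acid, standard code
  codons <- sort(names(code))       # lexicographic: deterministic ordering
  aas <- unname(code[codons])
  sym <- ifelse(aas == "*", "stop", tolower(aas))
  codon_tokens <- paste0(sym, "_", tolower(codons))

  masked_tokens <- paste0(letters[match(sort(setdiff(unique(aas), "*")),
                                        toupper(letters))], "_unk")
  specials <- c("unk", "cls", "sep", "pad", "mask")
  tokens <- c(codon_tokens, masked_tokens, specials)

  gc_count <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
                     integer(1))
  gc_fraction <- c(stats::setNames(gc_count / 3, codon_tokens),
                   stats::setNames(rep(0, length(masked_tokens) + length(specials)),
                                   c(masked_tokens, specials)))

  families <- split(codon_tokens, aas)
  families <- lapply(families, sort)

  structure(list(
    tokens = tokens,
    gc_fraction = gc_fraction,
    families = families,
    token_index = stats::setNames(seq_along(tokens), tokens),
    codon_of = stats::setNames(toupper(codons), codon_tokens),
    aa_of = stats::setNames(aas, codon_tokens)
  ), class = "codon_vocab")
}

#' @export
print.codon_vocab <- function(x, ...) {
  cat("codon_vocab:", length(x$tokens), "tokens (",
      length(x$codon_of), "codon-bearing,",
      sum(endsWith(x$tokens, "_unk") & x$tokens != "unk"), "masked,",
      "5 special )\n")
  invisible(x)
}

#' Tokenize a protein into masked amino-acid tokens
#'
#' Each residue becomes its masked token (`m_unk`, `a_unk`, ...), the input
#' representation from which codons are later predicted. Input is
#' case-insensitive; an optional trailing `*` (stop) is accepted and recorded
#' in the `has_stop` attribute rather than emitted as a token (stop codons are
#' chosen at decoding time).
#'
#' @param protein Amino-acid string using the 20 standard one-letter codes,
#'   optionally ending in `*`.
#' @param vocab A [build_vocabulary()] object.
#' @return Character vector of masked tokens with attribute `has_stop`.
#' @examples
#' tokenize_protein("MALW")  # m_unk a_unk l_unk w_unk
#' @export
tokenize_protein <- function(protein, vocab = build_vocabulary()) {
  stopifnot(is.character(protein), length(protein) == 1L)
  p <- toupper(protein)
  has_stop <- FALSE
  if (nchar(p) > 0L && substring(p, nchar(p)) == "*") {
    has_stop <- TRUE
    p <- substring(p, 1L, nchar(p) - 1L)
  }
  res <- strsplit(p, "")[[1]]
  bad <- which(!res %in% names(vocab$families) | res == "*")
  if (length(bad) > 0L) {
    stop("invalid amino-acid letter '", res[bad[1]], "' at position ", bad[1])
  }
  structure(if (length(res) == 0L) character(0) else paste0(tolower(res), "_unk"),
            has_stop = has_stop)
}

#' Tokenize an in-frame coding sequence into combined tokens
#'
#' Maps each codon of a CDS to its combined amino-acid/codon token via the
#' standard genetic code. A stop codon before the final position is an error
#' (truncated ORFs must not pass silently).
#'
#' @param dna In-frame DNA string over A/C/G/T, length divisible by 3.
#' @param vocab A [build_vocabulary()] object.
#' @return Character vector of codon-bearing tokens.
#' @examples
#' tokenize_cds("ATGTGG")  # m_atg w_tgg
#' @export
tokenize_cds <- function(dna, vocab = build_vocabulary()) {
  stopifnot(is.character(dna), length(dna) == 1L)
  d <- toupper(dna)
  if (grepl("[^ACGT]", d)) {
    stop("non-ACGT character at position ", regexpr("[^ACGT]", d))
  }
  if (nchar(d) %% 3L != 0L) stop("sequence length not divisible by 3")
  n <- nchar(d) %/% 3L
  if (n == 0L) return(character(0))
  cods <- substring(d, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  toks <- paste0(ifelse(vocab$aa_of[match(cods, vocab$codon_of)] == "*",
                        "stop", tolower(vocab$aa_of[match(cods, vocab$codon_of)])),
                 "_", tolower(cods))
  internal_stop <- which(vocab$aa_of[toks] == "*" & seq_len(n) < n)
  if (length(internal_stop) > 0L) {
    stop("internal stop codon at codon position ", internal_stop[1])
  }
  unname(toks)
}

#' Reassemble DNA from codon-bearing tokens
#'
#' Inverse of [tokenize_cds()]. Masked and special tokens carry no codon and
#' are rejected.
#'
#' @param tokens Character vector of codon-bearing tokens.
#' @param vocab A [build_vocabulary()] object.
#' @return Uppercase DNA string.
#' @export
detokenize <- function(tokens, vocab = build_vocabulary()) {
  if (length(tokens) == 0L) return("")
  cods <- vocab$codon_of[tokens]
  if (anyNA(cods)) {
    stop("token '", tokens[which(is.na(cods))[1]],
         "' is not a codon-bearing token and cannot be decoded to DNA")
  }
  paste(cods, collapse = "")
}

#' Translate a CDS with the standard genetic code
#'
#' Convenience wrapper over the vocabulary tables; stops translate to `*`.
#'
#' @inheritParams tokenize_cds
#' @return Amino-acid string (including `*` for stop codons).
#' @export
translate_cds <- function(dna, vocab = build_vocabulary()) {
  d <- toupper(dna)
  n <- nchar(d) %/% 3L
  if (n == 0L) return("")
  cods <- substring(d, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(vocab$aa_of[match(cods, vocab$codon_of)], collapse = "")
}
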