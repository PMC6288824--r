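# Cytosine sequence-context assignment (CG / CHG / CHH, H = A, C or T).

#' Assign the sequence context of a cytosine
#'
#' On the Watson strand a cytosine at `pos` is CG when the next base is G,
#' CHG when the pattern is C-H-G, and CHH otherwise. On the Crick strand the
#' same rule is applied to the reverse complement read 5'->3', i.e. the base
#' at `pos` must be G on Watson and the preceding Watson bases are
#' inspected. Cytosines too close to the chromosome end to resolve their
#' context return `NA` (ambiguous) and are excluded from analysis rather
#' than defaulted to CHH.
#'
#' @param seq Chromosome sequence: a single character string or a
#'   [Biostrings::DNAString].
#' @param pos 1-based position of the cytosine.
#' @param strand `"+"` (Watson) or `"-"` (Crick).
#' @return One of `"CG"`, `"CHG"`, `"CHH"`, or `NA_character_` when the
#'   context cannot be resolved.
#' @examples
#' assign_context("ACGT", 2, "+")  # CG
#' assign_context("ACAG", 2, "+")  # CHG
#' assign_context("TCGA", 3, "-")  # Crick C pairing the G reads 5'-CGA-3'
#' @export
assign_context <- function(seq, pos, strand) {
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  stopifnot(pos >= 1L, pos <= n, strand %in% c("+", "-"))
  base <- substr(seq, pos, pos)
  if (strand == "+") {
    if (base != "C") stop("base at pos on Watson strand is not C")
    if (pos + 1L > n) return(NA_character_)
    if (substr(seq, pos + 1L, pos + 1L) == "G") return("CG")
    if (pos + 2L > n) return(NA_character_)
    if (substr(seq, pos + 2L, pos + 2L) == "G") return("CHG") else return("CHH")
  }
  # Crick: cytosine pairs a Watson G; 5'->3' neighbours are pos-1, pos-2
  if (base != "G") stop("base at pos on Watson strand is not G (no Crick C)")
  if (pos - 1L < 1L) return(NA_character_)
  if (substr(seq, pos - 1L, pos - 1L) == "C") return("CG")
  if (pos - 2L < 1L) return(NA_character_)
  if (substr(seq, pos - 2L, pos - 2L) == "C") return("CHG") else return("CHH")
}

# Vectorized context scan of one chromosome. Returns a data.frame of all
# strand-specific cytosines with resolvable context, sorted by (pos, strand).
cytosine_contexts <- function(seq) {
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  is_c <- b == "C"
  is_g <- b == "G"
  nxt1 <- c(is_g[-1], NA)                      # base at pos+1 is G?
  nxt2 <- c(is_g[-(1:2)], NA, NA)              # base at pos+2 is G?
  prv1 <- c(NA, is_c[-n])                      # base at pos-1 is C?
  prv2 <- c(NA, NA, is_c[-((n - 1):n)])        # base at pos-2 is C?

  w_pos <- which(is_c)
  w_ctx <- ifelse(nxt1[w_pos], "CG",
                  ifelse(nxt2[w_pos], "CHG", "CHH"))
  w_ctx[w_pos == n] <- NA                      # no pos+1
  w_ctx[w_pos == n - 1L & !nxt1[w_pos]] <- NA  # no pos+2, not CG

  c_pos <- which(is_g)
  c_ctx <- ifelse(prv1[c_pos], "CG",
                  ifelse(prv2[c_pos], "CHG", "CHH"))
  c_ctx[c_pos == 1L] <- NA
  c_ctx[c_pos == 2L & !prv1[c_pos]] <- NA

  out <- data.frame(
    pos = c(w_pos, c_pos),
    strand = rep(c("+", "-"), c(length(w_pos), length(c_pos))),
    context = c(w_ctx, c_ctx),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$context), , drop = FALSE]
  out <- out[order(out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
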