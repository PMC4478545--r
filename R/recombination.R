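#' Recombination site definitions
#'
#' Holds the attP/attB attachment sites (each as left arm, core, right arm)
#' recombined by phiC31 integrase, and the 34-nt loxP site recognised by Cre
#' (13-nt inverted repeat, 8-nt asymmetric spacer, 13-nt inverted repeat; the
#' spacer asymmetry defines site orientation). attP and attB must share an
#' identical core (canonically the 3-nt `TTG`), at which crossover occurs.
#'
#' The default att arm sequences shipped here are synthetic placeholders of
#' realistic length around the canonical TTG core (the att variants used by
#' any particular vector should be supplied via [recombination_sites()] or a
#' YAML config, see [read_site_config()]). The default loxP is the canonical
#' published site.
#'
#' @param attP,attB Character vectors `c(left_arm, core, right_arm)`.
#' @param loxP Character vector `c(left_repeat, spacer, right_repeat)` with
#'   lengths 13, 8, 13.
#' @return A `recombination_sites` list with assembled `attP_seq`, `attB_seq`,
#'   `attL_seq`, `attR_seq`, `loxP_seq` strings.
#' @export
recombination_sites <- function(
    attP = c("CCCCAACTGGGGTAACCTTTGAGTTCTCTCAGT", "TTG", "GGGGTAACTAGTGCCCGGGGTGATCTCGTCGA"),
    attB = c("GGTGCCAGGGCGTGCCC", "TTG", "GGCTCCCCGGGCGCG"),
    loxP = c("ATAACTTCGTATA", "ATGTATGC", "TATACGAAGTTAT")) {
  check3 <- function(x, what) {
    if (!is.character(x) || length(x) != 3L) {
      agam_abort(sprintf("%s must be c(left, core/spacer, right)", what), "invalid_param")
    }
    lapply(x, assert_dna, what = what)
  }
  check3(attP, "attP")
  check3(attB, "attB")
  check3(loxP, "loxP")
  if (!identical(attP[2], attB[2])) {
    agam_abort("attP and attB must share an identical core", "invalid_param")
  }
  if (nchar(loxP[1]) != 13L || nchar(loxP[2]) != 8L || nchar(loxP[3]) != 13L) {
    agam_abort("loxP must be 13 + 8 + 13 nt", "invalid_param")
  }
  structure(
    list(
      attP = attP, attB = attB, loxP = loxP,
      core = attP[2],
      attP_seq = paste0(attP, collapse = ""),
      attB_seq = paste0(attB, collapse = ""),
      # crossover at the shared core: hybrid sites
      attL_seq = paste0(attB[1], attB[2], attP[3]),
      attR_seq = paste0(attP[1], attP[2], attB[3]),
      loxP_seq = paste0(loxP, collapse = "")
    ),
    class = "recombination_sites"
  )
}

#' Locate recombination sites on a molecule
#'
#' Exact-match calls of attP, attB, attL, attR, and loxP on both strands.
#'
#' @param mol A [dna_molecule()].
#' @param sites A [recombination_sites()] definition.
#' @return Data frame with columns `kind`, `position` (1-based top-strand
#'   start of the match; for `-` hits, of the site's reverse complement), and
#'   `strand`.
#' @export
find_recomb_sites <- function(mol, sites = recombination_sites()) {
  kinds <- c(
    attP = sites$attP_seq, attB = sites$attB_seq,
    attL = sites$attL_seq, attR = sites$attR_seq, loxP = sites$loxP_seq
  )
  seq <- mol$sequence
  len <- nchar(seq)
  out <- list()
  for (kind in names(kinds)) {
    site <- kinds[[kind]]
    scan <- if (mol$topology == "circular" && len >= nchar(site)) {
      paste0(seq, substr(seq, 1L, nchar(site) - 1L))
    } else {
      seq
    }
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") site else revcomp(site)
      hits <- motif_starts(scan, pat)
      hits <- hits[hits <= len]
      if (length(hits)) {
        out[[length(out) + 1L]] <- data.frame(
          kind = kind, position = hits, strand = strand, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(kind = character(0), position = integer(0), strand = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$kind), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' phiC31 integrase-mediated attB x attP integration
#'
#' Integrates a circular attB-bearing plasmid into the single attP site of a
#' linear locus. Crossover occurs at the shared core: the integrated plasmid
#' ends up flanked by the hybrid sites attR (attP-left + core + attB-right)
#' and attL (attB-left + core + attP-right), and neither attP nor attB
#' survives in the product. Total nucleotide content is conserved:
#' `length(product) = length(locus) + length(plasmid)`.
#'
#' @param locus Linear [dna_molecule()] containing exactly one attP (top
#'   strand).
#' @param plasmid Circular [dna_molecule()] containing exactly one attB (top
#'   strand).
#' @param sites A [recombination_sites()] definition.
#' @return The integrant as a linear `dna_molecule`, with `attR` and `attL`
#'   features annotated and the input features remapped.
#' @export
integrate_attB <- function(locus, plasmid, sites = recombination_sites()) {
  if (locus$topology != "linear") agam_abort("locus must be linear", "invalid_param")
  if (plasmid$topology != "circular") agam_abort("plasmid must be circular", "invalid_param")
  p_hits <- motif_starts(locus$sequence, sites$attP_seq)
  if (length(p_hits) != 1L) {
    agam_abort(
      sprintf("locus must contain exactly one attP (found %d)", length(p_hits)),
      "site_count_error"
    )
  }
  scan <- paste0(plasmid$sequence, substr(plasmid$sequence, 1L, nchar(sites$attB_seq) - 1L))
  b_hits <- motif_starts(scan, sites$attB_seq)
  b_hits <- b_hits[b_hits <= nchar(plasmid$sequence)]
  if (length(b_hits) != 1L) {
    agam_abort(
      sprintf("plasmid must contain exactly one attB (found %d)", length(b_hits)),
      "site_count_error"
    )
  }

  # rotate plasmid so attB starts at position 1
  pl <- rotate_molecule(plasmid, b_hits)
  lB <- nchar(sites$attB_seq)
  plasmid_rest <- substr(pl$sequence, lB + 1L, nchar(pl$sequence))

  p_start <- p_hits
  p_len <- nchar(sites$attP_seq)
  left <- substr(locus$sequence, 1L, p_start - 1L)
  right <- substr(locus$sequence, p_start + p_len, nchar(locus$sequence))

  n_PL <- nchar(sites$attP[1])
  n_core <- nchar(sites$core)
  n_BL <- nchar(sites$attB[1])
  n_BR <- nchar(sites$attB[3])
  n_PR <- nchar(sites$attP[3])

  seq <- paste0(
    left,
    sites$attR_seq, # attP_left + core + attB_right
    plasmid_rest,
    sites$attL_seq, # attB_left + core + attP_right
    right
  )

  attR_start <- nchar(left) + 1L
  attL_start <- nchar(left) + nchar(sites$attR_seq) + nchar(plasmid_rest) + 1L
  feats <- rbind(
    features_in_window(locus$features, 1L, nchar(left)),
    data.frame(
      name = "attR", start = attR_start,
      end = attR_start + nchar(sites$attR_seq) - 1L, strand = "+"
    ),
    shift_features(
      features_in_window(pl$features, lB + 1L, nchar(pl$sequence)),
      nchar(left) + nchar(sites$attR_seq)
    ),
    data.frame(
      name = "attL", start = attL_start,
      end = attL_start + nchar(sites$attL_seq) - 1L, strand = "+"
    ),
    shift_features(
      features_in_window(locus$features, p_start + p_len, nchar(locus$sequence)),
      p_start + p_len - 1L + nchar(seq) - nchar(locus$sequence)
    )
  )
  dna_molecule(paste0(locus$id, "_integrant"), seq, "linear", feats)
}

#' Cre/loxP recombination
#'
#' Applies Cre recombination between loxP sites. Two sites in direct repeat
#' (same strand) excise the intervening cassette: the parent molecule retains
#' a single loxP and the cassette circularises with the other loxP. Two sites
#' in inverted orientation flip the intervening segment in place. Nucleotide
#' content is conserved in every event. With more than two sites, all
#' pairwise outcomes are enumerated (pairs ordered by position, left-most
#' first); no kinetics is modelled.
#'
#' @param mol A linear [dna_molecule()] with at least two loxP sites; with
#'   fewer, the input is returned unchanged with a message.
#' @param sites A [recombination_sites()] definition.
#' @return A list of outcomes; each outcome is a list of `dna_molecule`s (for
#'   an excision: the shortened parent and the excised circle; for an
#'   inversion: the inverted molecule).
#' @export
cre_recombine <- function(mol, sites = recombination_sites()) {
  hits <- find_recomb_sites(mol, sites)
  hits <- hits[hits$kind == "loxP", , drop = FALSE]
  if (nrow(hits) < 2L) {
    message(sprintf("[%s] fewer than two loxP sites; molecule returned unchanged", mol$id))
    return(list(list(mol)))
  }
  lox_len <- nchar(sites$loxP_seq)
  pairs <- utils::combn(seq_len(nrow(hits)), 2L)
  outcomes <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    a <- hits[i, ]
    b <- hits[j, ]
    a1 <- a$position
    b1 <- a$position + lox_len - 1L
    a2 <- b$position
    b2 <- b$position + lox_len - 1L
    if (a$strand == b$strand) {
      # direct repeat: excision. Parent keeps the upstream loxP.
      parent_seq <- paste0(
        substr(mol$sequence, 1L, b1),
        substr(mol$sequence, b2 + 1L, nchar(mol$sequence))
      )
      circle_seq <- substr(mol$sequence, b1 + 1L, b2)
      parent_feats <- rbind(
        features_in_window(mol$features, 1L, b1),
        shift_features(
          features_in_window(mol$features, b2 + 1L, nchar(mol$sequence)),
          b1
        )
      )
      circle_feats <- features_in_window(mol$features, b1 + 1L, b2)
      outcomes[[k]] <- list(
        dna_molecule(paste0(mol$id, "_excised"), parent_seq, "linear", parent_feats),
        dna_molecule(paste0(mol$id, "_circle"), circle_seq, "circular", circle_feats)
      )
    } else {
      # inverted repeat: inversion of the intervening segment
      mid <- substr(mol$sequence, b1 + 1L, a2 - 1L)
      inv_seq <- paste0(
        substr(mol$sequence, 1L, b1),
        revcomp(mid),
        substr(mol$sequence, a2, nchar(mol$sequence))
      )
      tail_f <- features_in_window(mol$features, a2, nchar(mol$sequence))
      inv_feats <- rbind(
        features_in_window(mol$features, 1L, b1),
        local({
          f <- features_in_window(mol$features, b1 + 1L, a2 - 1L)
          if (nrow(f) > 0) {
            w <- nchar(mid)
            ns <- w - f$end + 1L
            ne <- w - f$start + 1L
            f$start <- ns
            f$end <- ne
            f$strand <- ifelse(f$strand == "+", "-", "+")
            f <- shift_features(f, b1)
          }
          f
        }),
        shift_features(tail_f, a2 - 1L)
      )
      outcomes[[k]] <- list(
        dna_molecule(paste0(mol$id, "_inverted"), inv_seq, "linear", inv_feats)
      )
    }
  }
  outcomes
}
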