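#' Define a type IIS restriction enzyme
#'
#' A type IIS enzyme cuts at fixed offsets 3' of its (asymmetric) recognition
#' motif, leaving programmable overhangs. For BsaI (`GGTCTC(1/5)`) the top
#' strand is cut 1 nt and the bottom strand 5 nt past the motif, producing
#' 4-nt 5' overhangs.
#'
#' @param name Enzyme name.
#' @param recognition Recognition motif (IUPAC allowed), top strand 5'->3'.
#' @param cut_offset_top,cut_offset_bottom Cut offsets, in nucleotides 3' of
#'   the recognition motif on each strand; the overhang length is
#'   `cut_offset_bottom - cut_offset_top` (must be > 0: 5' overhangs).
#' @return An `enzyme_spec` list.
#' @examples
#' bsai()
#' @export
enzyme_spec <- function(name, recognition, cut_offset_top, cut_offset_bottom) {
  recognition <- toupper(recognition)
  iupac_to_regex(recognition) # validates
  if (cut_offset_bottom <= cut_offset_top) {
    agam_abort("only 5' overhangs are modelled: cut_offset_bottom must exceed cut_offset_top", "invalid_param")
  }
  structure(
    list(
      name = name, recognition = recognition,
      cut_offset_top = as.integer(cut_offset_top),
      cut_offset_bottom = as.integer(cut_offset_bottom)
    ),
    class = "enzyme_spec"
  )
}

#' @rdname enzyme_spec
#' @export
bsai <- function() enzyme_spec("BsaI", "GGTCTC", 1L, 5L)

is_fixed_motif <- function(motif) !grepl("[^ACGT]", motif)

#' Find recognition sites of an enzyme
#'
#' Scans both strands of a molecule for the enzyme's recognition motif;
#' circular molecules are scanned across the origin.
#'
#' @param mol A [dna_molecule()].
#' @param enzyme An [enzyme_spec()] (default [bsai()]).
#' @return Data frame with columns `position` (1-based top-strand start of the
#'   motif occurrence; for `-` hits, of the motif's reverse complement) and
#'   `strand`.
#' @export
find_sites <- function(mol, enzyme = bsai()) {
  seq <- mol$sequence
  len <- nchar(seq)
  k <- nchar(enzyme$recognition)
  scan <- if (mol$topology == "circular" && len >= k) {
    paste0(seq, substr(seq, 1L, k - 1L))
  } else {
    seq
  }
  fixed <- is_fixed_motif(enzyme$recognition)
  top <- motif_starts(scan, enzyme$recognition, fixed = fixed)
  bot <- motif_starts(scan, revcomp_iupac(enzyme$recognition), fixed = fixed)
  top <- top[top <= len]
  bot <- bot[bot <= len]
  out <- data.frame(
    position = c(top, bot),
    strand = c(rep("+", length(top)), rep("-", length(bot))),
    stringsAsFactors = FALSE
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

# reverse complement honouring IUPAC ambiguity letters
revcomp_iupac <- function(motif) {
  comp <- c(
    A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
    K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
  )
  paste(rev(comp[strsplit(toupper(motif), "")[[1]]]), collapse = "")
}

# Cut coordinates: for each site, the 1-based position of the first base of
# the fragment to the right of the top-strand cut, plus the overhang label
# (the top-strand 4-mer spanning the staggered cut).
cut_positions <- function(mol, enzyme) {
  sites <- find_sites(mol, enzyme)
  len <- nchar(mol$sequence)
  k <- nchar(enzyme$recognition)
  ov <- enzyme$cut_offset_bottom - enzyme$cut_offset_top
  if (nrow(sites) == 0) {
    return(data.frame(cut = integer(0), label = character(0)))
  }
  cut <- ifelse(
    sites$strand == "+",
    sites$position + k + enzyme$cut_offset_top,
    sites$position - enzyme$cut_offset_bottom
  )
  if (mol$topology == "linear") {
    if (any(cut < 1L | cut + ov - 1L > len)) {
      agam_abort(
        sprintf("[%s] %s cut falls outside the linear molecule", mol$id, enzyme$name),
        "site_too_close_to_end"
      )
    }
    label <- substr(rep(mol$sequence, length(cut)), cut, cut + ov - 1L)
  } else {
    cut <- ((cut - 1L) %% len) + 1L
    label <- vapply(cut, function(p) subseq_circ(mol$sequence, p, p + ov - 1L), character(1))
  }
  out <- data.frame(cut = as.integer(cut), label = label, stringsAsFactors = FALSE)
  out <- out[!duplicated(out$cut), , drop = FALSE]
  out[order(out$cut), , drop = FALSE]
}

new_fragment <- function(seq, left, right, source, features = empty_features()) {
  structure(
    list(
      sequence = seq, left_overhang = left, right_overhang = right,
      source = source, features = features
    ),
    class = "overhang_fragment"
  )
}

#' @export
print.overhang_fragment <- function(x, ...) {
  lab <- function(l) if (nzchar(l)) l else "(blunt)"
  cat(sprintf(
    "<overhang_fragment> %d nt  %s ... %s  (from %s)\n",
    nchar(x$sequence), lab(x$left_overhang), lab(x$right_overhang), x$source
  ))
  invisible(x)
}

#' Digest a molecule with a type IIS enzyme
#'
#' Applies every cut of the enzyme and returns the resulting fragments with
#' their 4-nt sticky-end labels (top-strand convention). Fragment sequences
#' are the top strand between consecutive top-strand cuts, so digestion
#' conserves total nucleotide content. A circular molecule with k sites yields
#' k fragments; a linear one k+1 (outer ends blunt). Features fully inside a
#' fragment are carried along; features spanning a cut are dropped.
#'
#' Palindromic overhang labels are legal but flagged with a warning, since
#' they allow self-ligation.
#'
#' @param mol A [dna_molecule()].
#' @param enzyme An [enzyme_spec()].
#' @return List of `overhang_fragment` objects.
#' @export
digest <- function(mol, enzyme = bsai()) {
  cuts <- cut_positions(mol, enzyme)
  pal <- unique(cuts$label[vapply(cuts$label, is_palindromic, logical(1))])
  if (length(pal) > 0) {
    agam_warn(
      sprintf("[%s] palindromic overhang label(s) %s: self-ligation risk", mol$id, paste(pal, collapse = ", ")),
      "palindromic_overhang"
    )
  }
  len <- nchar(mol$sequence)
  if (nrow(cuts) == 0) {
    return(list(new_fragment(mol$sequence, "", "", mol$id, mol$features)))
  }
  if (mol$topology == "linear") {
    bounds <- c(1L, cuts$cut, len + 1L)
    labels <- c("", cuts$label, "")
    frags <- vector("list", nrow(cuts) + 1L)
    for (i in seq_along(frags)) {
      from <- bounds[i]
      to <- bounds[i + 1L] - 1L
      frags[[i]] <- new_fragment(
        substr(mol$sequence, from, to),
        left = labels[i], right = labels[i + 1L],
        source = mol$id,
        features = features_in_window(mol$features, from, to)
      )
    }
    frags
  } else {
    # rotate so the first cut is position 1, then treat as linear spans
    rot <- rotate_molecule(mol, cuts$cut[1])
    shift <- function(p) ((p - cuts$cut[1]) %% len) + 1L
    cut_r <- sort(shift(cuts$cut))
    lab_r <- cuts$label[order(shift(cuts$cut))]
    bounds <- c(cut_r, len + 1L)
    frags <- vector("list", nrow(cuts))
    for (i in seq_along(frags)) {
      from <- bounds[i]
      to <- bounds[i + 1L] - 1L
      frags[[i]] <- new_fragment(
        substr(rot$sequence, from, to),
        left = lab_r[i], right = lab_r[if (i == length(frags)) 1L else i + 1L],
        source = mol$id,
        features = features_in_window(rot$features, from, to)
      )
    }
    frags
  }
}

fragment_has_site <- function(frag, enzyme) {
  fixed <- is_fixed_motif(enzyme$recognition)
  length(motif_starts(frag$sequence, enzyme$recognition, fixed = fixed)) > 0 ||
    length(motif_starts(frag$sequence, revcomp_iupac(enzyme$recognition), fixed = fixed)) > 0
}

is_stuffer_fragment <- function(frag) {
  nrow(frag$features) > 0 && any(grepl("lacz|stuffer", tolower(frag$features$name)))
}

#' Simulate a GoldenGate restriction--ligation assembly
#'
#' Digests the destination vector and every donor with the assembly enzyme,
#' keeps the destination backbone (the released fragment free of recognition
#' sites and of the LacZ stuffer) and one insert per donor, and chains them by
#' overhang-label equality into the unique closed circle that uses the
#' backbone once and every insert exactly once. Successful assembly therefore
#' removes the stuffer and leaves no recognition site in the product.
#'
#' @param destination Circular [dna_molecule()] with at least two enzyme sites
#'   flanking a stuffer (feature named `lacZ`/`stuffer`).
#' @param donors List of [dna_molecule()] donors, each releasing exactly one
#'   insert fragment free of recognition sites.
#' @param enzyme An [enzyme_spec()].
#' @return An `assembly_product`: list with `molecule` (circular
#'   [dna_molecule()]), `fragment_ids` (ordered, backbone first), and
#'   `junction_labels` (ordered 4-mers).
#' @export
assemble <- function(destination, donors, enzyme = bsai()) {
  if (destination$topology != "circular") {
    agam_abort("destination must be circular", "invalid_param")
  }
  dest_frags <- digest(destination, enzyme)
  if (length(dest_frags) < 2L) {
    agam_abort("destination must carry at least two enzyme sites", "invalid_param")
  }
  backbone_idx <- which(
    !vapply(dest_frags, fragment_has_site, logical(1), enzyme = enzyme) &
      !vapply(dest_frags, is_stuffer_fragment, logical(1))
  )
  if (length(backbone_idx) == 0) {
    agam_abort("no release-able backbone fragment in the destination", "no_assembly")
  }
  if (length(backbone_idx) > 1) {
    agam_abort("multiple candidate backbone fragments in the destination", "ambiguous_assembly")
  }
  backbone <- dest_frags[[backbone_idx]]

  inserts <- lapply(donors, function(donor) {
    frags <- digest(donor, enzyme)
    cand <- Filter(function(f) !fragment_has_site(f, enzyme) && nzchar(f$left_overhang) &&
      nzchar(f$right_overhang), frags)
    if (length(cand) != 1L) {
      agam_abort(
        sprintf("donor '%s' releases %d candidate insert(s); expected exactly 1", donor$id, length(cand)),
        "bad_donor"
      )
    }
    cand[[1]]
  })

  frags <- c(list(backbone), inserts)
  lefts <- vapply(frags, `[[`, character(1), "left_overhang")
  if (anyDuplicated(lefts)) {
    agam_abort(
      sprintf("duplicated overhang label(s): %s", paste(unique(lefts[duplicated(lefts)]), collapse = ", ")),
      "ambiguous_assembly"
    )
  }

  order_idx <- 1L
  used <- c(TRUE, rep(FALSE, length(inserts)))
  current <- 1L
  junctions <- character(0)
  repeat {
    lab <- frags[[current]]$right_overhang
    nxt <- which(lefts == lab)
    if (length(nxt) == 0) {
      agam_abort(
        sprintf("no fragment accepts overhang '%s': assembly cannot close", lab),
        "no_assembly", data = list(dangling_label = lab)
      )
    }
    junctions <- c(junctions, lab)
    if (nxt == 1L) break
    if (used[nxt]) {
      agam_abort("assembly revisits a fragment before closing", "no_assembly")
    }
    used[nxt] <- TRUE
    order_idx <- c(order_idx, nxt)
    current <- nxt
  }
  if (!all(used)) {
    agam_abort(
      sprintf("assembly closed without %d donor insert(s)", sum(!used)),
      "no_assembly"
    )
  }

  seqs <- vapply(frags[order_idx], `[[`, character(1), "sequence")
  feats <- empty_features()
  offset <- 0L
  for (i in order_idx) {
    f <- frags[[i]]
    feats <- rbind(feats, shift_features(f$features, offset))
    offset <- offset + nchar(f$sequence)
  }
  product <- dna_molecule("assembly_product", paste0(seqs, collapse = ""), "circular", feats)
  if (nrow(find_sites(product, enzyme)) > 0) {
    agam_abort("assembled product retains a recognition site", "no_assembly")
  }
  structure(
    list(
      molecule = product,
      fragment_ids = vapply(frags[order_idx], `[[`, character(1), "source"),
      junction_labels = junctions
    ),
    class = "assembly_product"
  )
}

#' @export
print.assembly_product <- function(x, ...) {
  cat(sprintf(
    "<assembly_product> %d bp circular; %d fragments; junctions %s\n",
    nchar(x$molecule$sequence), length(x$fragment_ids), paste(x$junction_labels, collapse = "-")
  ))
  invisible(x)
}

#' Exact-match in-silico PCR
#'
#' Finds the forward primer on the top strand and the reverse primer's reverse
#' complement downstream of it, and returns the unique amplicon. Matching is
#' exact (no mismatch tolerance); primers must be at least 15 nt. Circular
#' templates may amplify across the origin.
#'
#' @param template A [dna_molecule()].
#' @param forward_primer,reverse_primer Primer sequences 5'->3'.
#' @return An `amplicon`: list with `sequence`, `length`, `forward_start`,
#'   `reverse_end` (1-based top-strand coordinates of the two primer 5' ends).
#'   Errors: `agam_no_amplicon` when a primer does not match,
#'   `agam_ambiguous_pcr` (carrying all products) when several pairings are
#'   valid.
#' @export
simulate_pcr <- function(template, forward_primer, reverse_primer) {
  forward_primer <- toupper(forward_primer)
  reverse_primer <- toupper(reverse_primer)
  assert_dna(forward_primer, "forward primer")
  assert_dna(reverse_primer, "reverse primer")
  if (nchar(forward_primer) < 15L || nchar(reverse_primer) < 15L) {
    agam_abort("primers must be at least 15 nt", "invalid_param")
  }
  seq <- template$sequence
  len <- nchar(seq)
  circular <- template$topology == "circular"
  scan <- if (circular) paste0(seq, seq) else seq
  f_hits <- motif_starts(scan, forward_primer)
  r_rc <- revcomp(reverse_primer)
  r_hits <- motif_starts(scan, r_rc)
  if (circular) f_hits <- f_hits[f_hits <= len]
  if (length(f_hits) == 0 || length(r_hits) == 0) {
    agam_abort("primer has no exact match on the template", "no_amplicon")
  }
  products <- list()
  for (f in f_hits) {
    for (r in r_hits) {
      r_end <- r + nchar(reverse_primer) - 1L
      size <- r_end - f + 1L
      ok <- r >= f && r_end >= f + nchar(forward_primer) - 1L
      if (circular) ok <- ok && size <= len
      if (ok) {
        key <- c(((f - 1L) %% len) + 1L, ((r_end - 1L) %% len) + 1L)
        products[[length(products) + 1L]] <- structure(
          list(
            sequence = substr(scan, f, r_end),
            length = size,
            forward_start = key[1],
            reverse_end = key[2]
          ),
          class = "amplicon"
        )
      }
    }
  }
  if (circular && length(products) > 1) {
    keys <- vapply(products, function(p) paste(p$forward_start, p$reverse_end), character(1))
    products <- products[!duplicated(keys)]
  }
  if (length(products) == 0) {
    agam_abort("primers match but in no amplifiable configuration", "no_amplicon")
  }
  if (length(products) > 1) {
    agam_abort(
      sprintf("%d distinct amplicons possible", length(products)),
      "ambiguous_pcr", data = list(products = products)
    )
  }
  products[[1]]
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf(
    "<amplicon> %d bp (top-strand %d..%d)\n",
    x$length, x$forward_start, x$reverse_end
  ))
  invisible(x)
}
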