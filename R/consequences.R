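CONSEQUENCE_CATEGORIES <- c(
  "synonymous", "missense_conservative", "missense_nonconservative",
  "nonsense", "sense", "frameshift", "inframe_indel", "start_loss", "complex"
)

#' Amino-acid substitution scoring matrix
#'
#' Wraps a log-odds substitution matrix (BLOSUM62 by default, taken from
#' \pkg{Biostrings}) together with the conservativeness threshold: an
#' exchange is called conservative iff `score(ref, alt) >= threshold`.
#' The default threshold 0 is the standard reading of "conservative by
#' BLOSUM62" (non-negative log-odds: the exchange is at least as likely as
#' expected by chance within related proteins).
#'
#' @param name Matrix name; `"BLOSUM62"` is the only one bundled upstream
#'   that this wrapper loads by name.
#' @param threshold Integer score threshold for conservativeness.
#' @return A `SubstitutionMatrix` object.
#' @export
substitution_matrix <- function(name = "BLOSUM62", threshold = 0L) {
  env <- new.env()
  ok <- tryCatch({
    suppressWarnings(utils::data(list = name, package = "Biostrings", envir = env))
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !exists(name, envir = env)) {
    stop("unknown substitution matrix '", name, "'")
  }
  m <- get(name, envir = env)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
  m <- m[aa, aa]
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix not symmetric")
  structure(list(name = name, score = m, threshold = as.integer(threshold)),
            class = "SubstitutionMatrix")
}

substitution_score <- function(matrix, a, b) {
  if (!a %in% rownames(matrix$score) || !b %in% rownames(matrix$score)) {
    return(NA_integer_)
  }
  matrix$score[a, b]
}

#' Inactivating-category policy
#'
#' The default policy counts stop-gains (nonsense), frameshifts, start-losses
#' and stop-losses (sense) as CDS-inactivating; `"include-inframe"` adds
#' in-frame indels, which insert or delete whole codons and can equally
#' disrupt essential residues.
#'
#' @param policy `"default"`, `"include-inframe"`, or a character vector of
#'   category names.
#' @return Character vector of inactivating categories.
#' @export
inactivating_policy <- function(policy = "default") {
  if (length(policy) == 1L && policy %in% c("default", "include-inframe")) {
    base <- c("nonsense", "frameshift", "start_loss", "sense")
    if (policy == "include-inframe") base <- c(base, "inframe_indel")
    return(base)
  }
  bad <- setdiff(policy, CONSEQUENCE_CATEGORIES)
  if (length(bad) > 0L) stop("unknown categories in policy: ",
                             paste(bad, collapse = ", "))
  policy
}

#' Is a consequence CDS-inactivating?
#'
#' @param category Consequence category (vectorized).
#' @param policy See [inactivating_policy()].
#' @return Logical vector.
#' @export
is_cds_inactivating <- function(category, policy = "default") {
  category %in% inactivating_policy(policy)
}

variant_shape <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) {
    if (nr == 1L) "snv" else "mnv"
  } else if (nr == 1L && na > 1L && substr(alt, 1L, 1L) == ref) {
    "insertion"
  } else if (na == 1L && nr > 1L && substr(ref, 1L, 1L) == alt) {
    "deletion"
  } else {
    "complex"
  }
}

#' Locate a variant in gene space
#'
#' Reports one record per gene whose CDS overlaps the changed bases of the
#' (normalized) variant, with the 1-based strand-corrected offset into the
#' spliced CDS; a single intergenic record when no gene is hit. Overlapping
#' genes therefore yield multiple records.
#'
#' For an insertion the relevant offset is that of the transcript base
#' 5' of the insertion point; for a deletion, the transcript-5'-most deleted
#' base. An indel whose changed bases only partly overlap a CDS is flagged
#' `boundary = TRUE` (classified `complex` downstream).
#'
#' @param chrom,pos,ref,alt Normalized variant fields.
#' @param genes Named list of `GeneModel` objects.
#' @return Data frame with columns `region` (`"CDS"`/`"intergenic"`),
#'   `gene_id`, `cds_offset`, `boundary`.
#' @export
locate_variant <- function(chrom, pos, ref, alt, genes) {
  shape <- variant_shape(ref, alt)
  nr <- nchar(ref)
  changed <- switch(shape,
    snv = pos,
    mnv = seq.int(pos, pos + nr - 1L),
    insertion = c(pos, pos + 1L),   # flanks of the insertion point
    deletion = seq.int(pos + 1L, pos + nr - 1L),
    complex = seq.int(pos, pos + max(nr, 1L) - 1L)
  )
  fs <- min(changed); fe <- max(changed)
  rows <- list()
  for (g in genes) {
    if (g$chromosome != chrom) next
    sp <- gene_span(g)
    if (fe < sp[1L] || fs > sp[2L]) next
    offs <- vapply(changed, function(p) cds_offset_of(g, p), integer(1L))
    n_in <- sum(!is.na(offs))
    if (n_in == 0L) next
    if (shape == "insertion") {
      # in-CDS only when both flanks are coding (offsets are then adjacent)
      if (n_in == 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = "CDS", gene_id = g$gene_id,
          cds_offset = min(offs), boundary = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          region = "CDS", gene_id = g$gene_id,
          cds_offset = offs[!is.na(offs)][1L], boundary = TRUE)
      }
    } else {
      full <- n_in == length(offs)
      rows[[length(rows) + 1L]] <- data.frame(
        region = "CDS", gene_id = g$gene_id,
        cds_offset = min(offs, na.rm = TRUE),
        boundary = !full || shape == "complex")
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(region = "intergenic", gene_id = NA_character_,
                      cds_offset = NA_integer_, boundary = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify a single-nucleotide substitution in a CDS
#'
#' Rebuilds the affected codon with the alternate base (strand-corrected)
#' and compares the encoded amino acids. Categories: `synonymous` (amino
#' acid unchanged, including stop-to-stop), `start_loss` (codon 1 ATG
#' destroyed), `sense` (stop-loss: stop codon to sense codon), `nonsense`
#' (stop-gain), otherwise missense split into conservative and
#' non-conservative by the substitution matrix. Notation is
#' `<refAA><codon><altAA>` with `*` for stop (e.g. `Q5*`).
#'
#' @param gene A `GeneModel`.
#' @param cds The gene's `CodingSequence`.
#' @param cds_offset 1-based offset of the substituted base in the spliced
#'   CDS.
#' @param ref,alt Single-base genomic alleles.
#' @param matrix A `SubstitutionMatrix`.
#' @return One-row data frame with `category`, `codon_index`, `ref_aa`,
#'   `alt_aa`, `notation`.
#' @export
classify_substitution <- function(gene, cds, cds_offset, ref, alt, matrix) {
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    stop("classify_substitution() requires single-base alleles")
  }
  rb <- if (gene$strand == "-") comp_base(ref) else ref
  ab <- if (gene$strand == "-") comp_base(alt) else alt
  nt <- cds$nucleotides
  if (substr(nt, cds_offset, cds_offset) != rb) {
    stop("gene ", gene$gene_id, ": CDS base at offset ", cds_offset,
         " does not match strand-corrected ref allele")
  }
  ci <- (cds_offset - 1L) %/% 3L + 1L
  within <- (cds_offset - 1L) %% 3L + 1L
  ref_codon <- substr(nt, 3L * ci - 2L, 3L * ci)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- ab
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  category <- if (ref_aa == "X" || alt_aa == "X") {
    "complex"
  } else if (ref_aa == alt_aa) {
    "synonymous"
  } else if (ci == 1L && ref_codon == "ATG") {
    "start_loss"
  } else if (ref_aa == "*") {
    "sense"
  } else if (alt_aa == "*") {
    "nonsense"
  } else {
    sc <- substitution_score(matrix, ref_aa, alt_aa)
    if (!is.na(sc) && sc >= matrix$threshold) {
      "missense_conservative"
    } else {
      "missense_nonconservative"
    }
  }
  data.frame(category = category, codon_index = ci,
             ref_aa = ref_aa, alt_aa = alt_aa,
             notation = paste0(ref_aa, ci, alt_aa))
}

#' Classify an insertion or deletion in a CDS
#'
#' Net length change not divisible by 3 is a `frameshift`; divisible by 3 an
#' `inframe_indel`. Indels whose changed bases span a CDS boundary are
#' `complex`. Notation is nucleotide-level, strand-corrected: insertions
#' `+SEQ p/p+1` (inserted between spliced-CDS offsets p and p+1), deletions
#' `-SEQ p` (deletion starting at offset p).
#'
#' @param gene A `GeneModel`.
#' @param cds The gene's `CodingSequence`.
#' @param location One row of [locate_variant()] output for this gene.
#' @param ref,alt Anchored genomic alleles.
#' @return One-row data frame with `category`, `codon_index`, `ref_aa`,
#'   `alt_aa` (both `NA`), `notation`.
#' @export
classify_indel <- function(gene, cds, location, ref, alt) {
  shape <- variant_shape(ref, alt)
  p <- location$cds_offset
  ci <- (p - 1L) %/% 3L + 1L
  if (isTRUE(location$boundary) || shape %in% c("complex", "snv", "mnv")) {
    return(data.frame(category = "complex", codon_index = ci,
                      ref_aa = NA_character_, alt_aa = NA_character_,
                      notation = sprintf("%s>%s %d", ref, alt, p)))
  }
  net <- nchar(alt) - nchar(ref)
  category <- if (net %% 3L == 0L) "inframe_indel" else "frameshift"
  if (shape == "insertion") {
    seq <- substr(alt, 2L, nchar(alt))
    if (gene$strand == "-") seq <- revcomp(seq)
    notation <- sprintf("+%s %d/%d", seq, p, p + 1L)
  } else {
    seq <- substr(ref, 2L, nchar(ref))
    if (gene$strand == "-") seq <- revcomp(seq)
    notation <- sprintf("-%s %d", seq, p)
  }
  data.frame(category = category, codon_index = ci,
             ref_aa = NA_character_, alt_aa = NA_character_,
             notation = notation)
}

# split an MNV (equal-length multi-base substitution) into per-base SNVs at
# the differing positions
decompose_mnv <- function(chrom, pos, ref, alt) {
  n <- nchar(ref)
  rb <- strsplit(ref, "")[[1L]]
  ab <- strsplit(alt, "")[[1L]]
  diff <- which(rb != ab)
  data.frame(chrom = chrom, pos = pos + diff - 1L,
             ref = rb[diff], alt = ab[diff])
}

#' Annotate variants with their CDS consequences
#'
#' End-to-end consequence calling: variants are normalized, multi-base
#' equal-length substitutions are decomposed into per-base SNVs, each variant
#' is located against every overlapping gene, and located variants are
#' classified at codon level. Genes whose CDS length is not divisible by 3
#' are reported (`region = "CDS"`) but not classified (`category = NA`).
#' A variant overlapping k genes yields k rows.
#'
#' @param variants A `StrainVariantSet` or data frame with
#'   `chrom`/`pos`/`ref`/`alt`.
#' @param genome A `Genome`.
#' @param genes Named list of `GeneModel` objects.
#' @param matrix A `SubstitutionMatrix`; see [substitution_matrix()].
#' @param policy Inactivating policy; see [inactivating_policy()].
#' @return Data frame with one row per variant-gene pair (plus one row per
#'   intergenic variant): `chrom`, `pos`, `ref`, `alt`, `region`, `gene_id`,
#'   `symbol`, `cds_offset`, `category`, `codon_index`, `ref_aa`, `alt_aa`,
#'   `notation`, `inactivating`, `codon_shared` (TRUE when another variant
#'   hits the same codon of the same gene).
#' @export
annotate_variants <- function(variants, genome, genes,
                              matrix = substitution_matrix(),
                              policy = "default") {
  df <- if (inherits(variants, "StrainVariantSet")) variants$variants
        else as.data.frame(variants)
  empty <- data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), region = character(0), gene_id = character(0),
    symbol = character(0), cds_offset = integer(0), category = character(0),
    codon_index = integer(0), ref_aa = character(0), alt_aa = character(0),
    notation = character(0), inactivating = logical(0),
    codon_shared = logical(0))
  if (nrow(df) == 0L) return(empty)
  df <- normalize_variant_table(df, genome)

  # decompose MNVs into independent per-base SNVs
  pieces <- list()
  for (i in seq_len(nrow(df))) {
    if (variant_shape(df$ref[i], df$alt[i]) == "mnv") {
      pieces[[length(pieces) + 1L]] <-
        decompose_mnv(df$chrom[i], df$pos[i], df$ref[i], df$alt[i])
    } else {
      pieces[[length(pieces) + 1L]] <- df[i, c("chrom", "pos", "ref", "alt")]
    }
  }
  df <- do.call(rbind, pieces)
  rownames(df) <- NULL

  cds_cache <- list()
  get_cds <- function(g) {
    if (is.null(cds_cache[[g$gene_id]])) {
      cds_cache[[g$gene_id]] <<- suppressWarnings(extract_cds(g, genome))
    }
    cds_cache[[g$gene_id]]
  }

  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    loc <- locate_variant(df$chrom[i], df$pos[i], df$ref[i], df$alt[i], genes)
    rows <- vector("list", nrow(loc))
    for (j in seq_len(nrow(loc))) {
      l <- loc[j, ]
      base <- data.frame(chrom = df$chrom[i], pos = df$pos[i],
                         ref = df$ref[i], alt = df$alt[i],
                         region = l$region, gene_id = l$gene_id,
                         symbol = NA_character_,
                         cds_offset = l$cds_offset)
      cls <- data.frame(category = NA_character_, codon_index = NA_integer_,
                        ref_aa = NA_character_, alt_aa = NA_character_,
                        notation = NA_character_)
      if (l$region == "CDS") {
        g <- genes[[l$gene_id]]
        base$symbol <- g$symbol
        if (g$coding_ok) {
          cds <- get_cds(g)
          shape <- variant_shape(df$ref[i], df$alt[i])
          cls <- if (shape == "snv" && !isTRUE(l$boundary)) {
            classify_substitution(g, cds, l$cds_offset,
                                  df$ref[i], df$alt[i], matrix)
          } else {
            classify_indel(g, cds, l, df$ref[i], df$alt[i])
          }
        }
      }
      rows[[j]] <- cbind(base, cls)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  ann$inactivating <- !is.na(ann$category) &
    is_cds_inactivating(ann$category, policy)
  codon_key <- ifelse(is.na(ann$codon_index), NA_character_,
                      paste(ann$gene_id, ann$codon_index))
  shared <- codon_key %in% codon_key[duplicated(codon_key) & !is.na(codon_key)]
  ann$codon_shared <- shared & !is.na(codon_key)
  if (any(ann$codon_shared)) {
    message(sum(ann$codon_shared),
            " consequence(s) share a codon with another variant")
  }
  ann <- ann[order(ann$chrom, ann$pos, ann$ref, ann$alt), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Summarize classified consequences
#'
#' Counts per category over variant-gene pairs (a variant overlapping k
#' genes contributes k), plus the number of distinct variants, distinct
#' affected genes, and CDS-inactivating calls.
#'
#' @param ann Output of [annotate_variants()].
#' @return A `ConsequenceSummary` (list with `counts`, `n_variants`,
#'   `n_distinct_variants`, `n_genes_affected`, `n_inactivating`,
#'   `n_intergenic`, `schema_version`).
#' @export
summarize_consequences <- function(ann) {
  cl <- ann[ann$region == "CDS" & !is.na(ann$category), , drop = FALSE]
  counts <- vapply(CONSEQUENCE_CATEGORIES,
                   function(cat) sum(cl$category == cat), integer(1L))
  structure(list(
    counts = as.list(counts),
    n_variants = nrow(cl),
    n_distinct_variants = length(unique(variant_key(cl))),
    n_genes_affected = length(unique(cl$gene_id)),
    n_inactivating = sum(cl$inactivating),
    n_intergenic = sum(ann$region == "intergenic"),
    schema_version = "1.0"
  ), class = "ConsequenceSummary")
}

#' @export
print.ConsequenceSummary <- function(x, ...) {
  miss <- x$counts$missense_conservative + x$counts$missense_nonconservative
  cat(sprintf(paste0(
    "%d coding variant-gene pair(s) affecting %d coding sequence(s)\n",
    "  missense: %d (%d conservative, %d non-conservative)\n",
    "  nonsense: %d  sense (stop-loss): %d  start-loss: %d\n",
    "  frameshift: %d  in-frame indel: %d  synonymous: %d  complex: %d\n",
    "  CDS-inactivating: %d   intergenic variants: %d\n"),
    x$n_variants, x$n_genes_affected,
    miss, x$counts$missense_conservative, x$counts$missense_nonconservative,
    x$counts$nonsense, x$counts$sense, x$counts$start_loss,
    x$counts$frameshift, x$counts$inframe_indel, x$counts$synonymous,
    x$counts$complex, x$n_inactivating, x$n_intergenic))
  invisible(x)
}

#' Per-gene variation report
#'
#' One row per affected gene in the style of a comparative-genomics summary
#' table: chromosome, gene id, symbol, description, CDS length in codons
#' (stop codon included), and all variations joined with `"; "` in spliced-CDS
#' order. Rows are sorted by chromosome (genome order when a `Genome` is
#' supplied) and then by gene start coordinate.
#'
#' @param ann Output of [annotate_variants()].
#' @param genes Named list of `GeneModel` objects.
#' @param genome Optional `Genome` fixing the chromosome sort order.
#' @param inactivating_only Restrict to genes carrying at least one
#'   CDS-inactivating consequence; their non-synonymous variations are then
#'   all listed (a gene hit by both a missense and a stop-gain shows both).
#' @return Data frame with columns `chromosome`, `gene_id`, `symbol`,
#'   `description`, `cds_length`, `variation`.
#' @export
format_gene_report <- function(ann, genes, genome = NULL,
                               inactivating_only = FALSE) {
  cl <- ann[ann$region == "CDS" & !is.na(ann$category), , drop = FALSE]
  if (inactivating_only) {
    keep_genes <- unique(cl$gene_id[cl$inactivating])
    cl <- cl[cl$gene_id %in% keep_genes & cl$category != "synonymous", ,
             drop = FALSE]
  }
  out <- data.frame(chromosome = character(0), gene_id = character(0),
                    symbol = character(0), description = character(0),
                    cds_length = integer(0), variation = character(0))
  if (nrow(cl) == 0L) return(out)
  for (gid in unique(cl$gene_id)) {
    g <- genes[[gid]]
    sub <- cl[cl$gene_id == gid, , drop = FALSE]
    sub <- sub[order(sub$cds_offset), , drop = FALSE]
    out <- rbind(out, data.frame(
      chromosome = g$chromosome, gene_id = gid, symbol = g$symbol,
      description = g$description, cds_length = g$length_codons,
      variation = paste(sub$notation, collapse = "; ")))
  }
  chrom_levels <- if (!is.null(genome)) names(genome) else sort(unique(out$chromosome))
  starts <- vapply(out$gene_id, function(id) gene_span(genes[[id]])[1L],
                   numeric(1L))
  out <- out[order(match(out$chromosome, chrom_levels), starts), , drop = FALSE]
  rownames(out) <- NULL
  out
}
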