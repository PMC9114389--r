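# Downstream screening of enamel-proteome peptide-spectrum-match (PSM)
# tables. Sequence matching treats I and L as equivalent throughout
# (mass-indistinguishable residues).

il_normalise <- function(x) gsub("I", "L", x, fixed = TRUE)

parse_pairs <- function(s) {
  # "pos:val;pos:val;..." -> tibble(pos, val); empty/NA -> 0 rows
  if (is.na(s) || !nzchar(s)) return(tibble(pos = integer(), val = character()))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  tibble(pos = as.integer(purrr::map_chr(kv, 1)),
         val = purrr::map_chr(kv, 2))
}

#' Read a PSM table
#'
#' Tab-separated columns: `peptide`, `protein`, `start` (1-based position
#' of the peptide in the protein), `modifications` ("pos:name;..."
#' positions within the peptide), `site_support` ("pos:0|1;..."
#' fragmentation support per position of interest), `is_blank` (0/1,
#' spectra from extraction/instrument blanks). A `score` column is
#' accepted but unused.
#'
#' @param path TSV file path.
#' @return Tibble with list-columns `mods` and `support`.
#' @export
read_psm_tsv <- function(path) {
  data <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("peptide", "protein", "start"), names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!"modifications" %in% names(data)) data$modifications <- ""
  if (!"site_support" %in% names(data)) data$site_support <- ""
  if (!"is_blank" %in% names(data)) data$is_blank <- 0
  psm_table(data$peptide, data$protein, data$start, data$modifications,
            data$site_support, as.logical(data$is_blank))
}

#' Assemble a PSM table from vectors
#'
#' @param peptide Peptide sequences (upper-case residues).
#' @param protein Protein accession/name per PSM.
#' @param start 1-based start position of the peptide in the protein.
#' @param modifications Strings "pos:name;..." (positions within the
#'   peptide) or a list of data frames with `pos`, `val`.
#' @param site_support Strings "pos:0|1;..." flagging per-position
#'   fragmentation support, or a list of data frames.
#' @param is_blank Logical: PSM originates from a blank run.
#' @return Tibble of class `psm_table` with list-columns `mods`,
#'   `support`.
#' @export
psm_table <- function(peptide, protein, start = 1L, modifications = "",
                      site_support = "", is_blank = FALSE) {
  n <- length(peptide)
  tb <- tibble(
    peptide = toupper(peptide),
    protein = rep_len(protein, n),
    start = as.integer(rep_len(start, n)),
    is_blank = rep_len(as.logical(is_blank), n)
  )
  if (any(tb$start < 1)) abort("start positions must be >= 1")
  mk <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
      purrr::map(rep_len(x, n), as_tibble)
    } else {
      purrr::map(rep_len(as.character(x), n), parse_pairs)
    }
  }
  tb$mods <- mk(modifications)
  tb$support <- mk(site_support)
  bad <- purrr::map2_lgl(tb$mods, nchar(tb$peptide), function(m, len) {
    nrow(m) > 0 && (any(m$pos < 1) || any(m$pos > len))
  })
  if (any(bad)) abort("modification position outside its peptide")
  class(tb) <- c("psm_table", class(tb))
  tb
}

#' Remove blanks, single-peptide proteins and contaminants
#'
#' The standard pre-filter for ancient-enamel PSM statistics: spectra from
#' blank runs are dropped, as are proteins represented by a single
#' distinct peptide and proteins on the contaminant list.
#'
#' @param table A [psm_table()].
#' @param contaminants Character vector of contaminant protein names.
#' @return Filtered `psm_table`.
#' @export
filter_psms <- function(table, contaminants = character()) {
  table <- table[!table$is_blank, ]
  pep_per_prot <- tapply(il_normalise(table$peptide), table$protein,
                         function(x) length(unique(x)))
  keep_prot <- names(pep_per_prot)[pep_per_prot >= 2]
  keep_prot <- setdiff(keep_prot, contaminants)
  table[table$protein %in% keep_prot, ]
}

#' Relative spectral count of a post-translational modification
#'
#' The number of (non-blank) PSMs carrying the modification on a target
#' residue, divided by the number of PSMs containing at least one target
#' residue, as a percentage.
#'
#' @param table A [psm_table()].
#' @param ptm Modification name, e.g. `"Phospho"`, `"Deamidation"`.
#' @param target_residues Character vector of modifiable residues, e.g.
#'   `c("S","T","Y")` or `c("N","Q")`.
#' @return One-row tibble: `ptm`, `rate_pct` (NA with `undefined = TRUE`
#'   when no PSM contains a target residue), `n_modified`, `n_with_residue`.
#' @export
ptm_rate <- function(table, ptm, target_residues) {
  table <- table[!table$is_blank, ]
  if (!nrow(table)) {
    return(tibble(ptm = ptm, rate_pct = NA_real_, n_modified = 0L,
                  n_with_residue = 0L, undefined = TRUE))
  }
  pat <- paste0("[", paste(target_residues, collapse = ""), "]")
  has_res <- grepl(pat, table$peptide)
  carries <- purrr::map2_lgl(table$mods, table$peptide, function(m, pep) {
    if (!nrow(m)) return(FALSE)
    hit <- m$val == ptm &
      substr(pep, m$pos, m$pos) %in% target_residues
    any(hit)
  })
  denom <- sum(has_res)
  num <- sum(carries & has_res)
  tibble(ptm = ptm,
         rate_pct = if (denom == 0) NA_real_ else 100 * num / denom,
         n_modified = num, n_with_residue = denom,
         undefined = denom == 0)
}

#' Sequence context of phosphorylated serines and the S-x-E motif
#'
#' Tallies residues at offsets -5..+5 around each phospho-serine site
#' (within peptide bounds) and the fraction of sites with glutamate at +2
#' (the S-x-E kinase motif of enamel proteins). Sites whose +2 position
#' falls outside the peptide are excluded from the motif denominator.
#'
#' @param table A [psm_table()].
#' @param mod_name Phosphorylation label in the table (default
#'   `"Phospho"`).
#' @param offsets Context window (default -5..5).
#' @return List: `counts` (tibble offset, residue, n), `sxe_fraction`,
#'   `n_sites`, `n_sites_with_plus2`.
#' @export
phospho_motif <- function(table, mod_name = "Phospho", offsets = -5:5) {
  table <- table[!table$is_blank, ]
  sites <- purrr::map2(table$mods, table$peptide, function(m, pep) {
    if (!nrow(m)) return(NULL)
    ps <- m$pos[m$val == mod_name & substr(pep, m$pos, m$pos) == "S"]
    if (!length(ps)) return(NULL)
    tibble(pep = pep, pos = ps)
  })
  sites <- dplyr::bind_rows(sites)
  if (!nrow(sites)) abort("no phosphorylated serine PSMs in the table")
  ctx <- purrr::map(seq_len(nrow(sites)), function(i) {
    pep <- sites$pep[i]
    p <- sites$pos[i]
    at <- p + offsets
    ok <- at >= 1 & at <= nchar(pep)
    tibble(offset = offsets[ok], residue = substring(pep, at[ok], at[ok]))
  })
  ctx <- dplyr::bind_rows(ctx)
  counts <- dplyr::count(ctx, .data$offset, .data$residue, name = "n")
  plus2 <- sites$pos + 2 <= nchar(sites$pep)
  sxe <- substr(sites$pep, sites$pos + 2, sites$pos + 2) == "E" & plus2
  list(counts = counts,
       sxe_fraction = if (any(plus2)) sum(sxe) / sum(plus2) else NA_real_,
       n_sites = nrow(sites), n_sites_with_plus2 = sum(plus2))
}

#' Coverage of lineage-diagnostic amino-acid positions
#'
#' For each panel site, reports whether any non-blank PSM spans it, whether
#' the spanning spectra have fragmentation support at the site (unsupported
#' spectra are excluded), the observed residue (I/L-equivalent), and the
#' lineages compatible with it. The overall call is the most exclusive
#' taxon set consistent with all supported, conflict-free sites.
#'
#' @param table A [psm_table()].
#' @param panel Data frame with columns `protein`, `position`, `lineage`,
#'   `residue` (expected residue of each lineage at the site).
#' @param homo_lineages Lineages forming the genus-Homo ingroup; when the
#'   resolved sites exclude only the outgroups the call is "genus Homo,
#'   within-Homo indeterminate".
#' @return List: `sites` tibble (`protein`, `position`, `covered`,
#'   `supported`, `observed`, `conflict`, `compatible`), `compatible`
#'   (lineages consistent with all usable sites), `call` (text).
#' @export
diagnostic_coverage <- function(table, panel,
                                homo_lineages = c("H_sapiens", "Neanderthal",
                                                  "Denisovan", "Xiahe_Denisovan")) {
  panel <- as_tibble(panel)
  if (!nrow(panel)) abort("empty site panel")
  table <- table[!table$is_blank, ]
  all_lin <- sort(unique(panel$lineage))
  keys <- dplyr::distinct(panel, .data$protein, .data$position)
  site_rows <- purrr::map(seq_len(nrow(keys)), function(i) {
    prot <- keys$protein[i]
    pos <- keys$position[i]
    pan <- panel[panel$protein == prot & panel$position == pos, ]
    span <- table$protein == prot & table$start <= pos &
      (table$start + nchar(table$peptide) - 1L) >= pos
    covered <- any(span)
    observed <- character()
    supported <- FALSE
    if (covered) {
      idx <- which(span)
      for (j in idx) {
        pep_pos <- pos - table$start[j] + 1L
        sup <- table$support[[j]]
        ok <- nrow(sup) > 0 && any(sup$pos == pep_pos & sup$val %in% c("1", "TRUE"))
        if (ok) {
          supported <- TRUE
          observed <- c(observed, il_normalise(substr(table$peptide[j],
                                                      pep_pos, pep_pos)))
        }
      }
    }
    observed <- unique(observed)
    conflict <- length(observed) > 1
    compatible <- if (supported && !conflict && length(observed) == 1) {
      pan$lineage[il_normalise(pan$residue) == observed]
    } else NA
    tibble(protein = prot, position = pos, covered = covered,
           supported = supported,
           observed = if (length(observed) == 1 && !conflict) observed else NA_character_,
           conflict = conflict,
           compatible = list(compatible))
  })
  sites <- dplyr::bind_rows(site_rows)
  usable <- sites$supported & !sites$conflict
  compat <- all_lin
  for (i in which(usable)) {
    compat <- intersect(compat, sites$compatible[[i]])
  }
  homo_present <- intersect(homo_lineages, all_lin)
  call <- if (!any(usable)) {
    "indeterminate: no supported diagnostic site"
  } else if (setequal(compat, all_lin)) {
    "indeterminate: supported sites do not discriminate"
  } else if (setequal(compat, homo_present)) {
    "genus Homo, within-Homo indeterminate"
  } else if (!length(compat)) {
    "no lineage consistent with all supported sites"
  } else {
    paste("consistent with:", paste(sort(compat), collapse = ", "))
  }
  list(sites = sites, compatible = compat, call = call)
}

#' Amelogenin-Y screening for skeletal sex
#'
#' Detects AMELY-specific peptides (exact subsequence match after I/L
#' normalisation) among non-blank PSMs. Absence of AMELY is never reported
#' as a bare female call: degradation below the detection limit is an
#' explicit alternative.
#'
#' @param table A [psm_table()].
#' @param amely_specific_peptides Character vector of peptides unique to
#'   amelogenin-Y (not shared with AMELX).
#' @return List: `amely_detected`, `matches` (tibble of matched PSMs),
#'   `inference` text.
#' @export
amely_screen <- function(table, amely_specific_peptides) {
  if (!length(amely_specific_peptides)) abort("empty AMELY reference set")
  table <- table[!table$is_blank, ]
  refs <- il_normalise(toupper(amely_specific_peptides))
  peps <- il_normalise(table$peptide)
  hit <- purrr::map_lgl(peps, function(p) any(purrr::map_lgl(refs, ~ grepl(.x, p, fixed = TRUE))))
  detected <- any(hit)
  list(
    amely_detected = detected,
    matches = table[hit, c("peptide", "protein", "start")],
    inference = if (detected) "male" else "female or degraded beyond detection"
  )
}
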