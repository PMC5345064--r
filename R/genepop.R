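#' Read a Genepop file
#'
#' Parses the common 3-digit (or 2-digit) Genepop dialect: a title line,
#' locus names (one per line or comma-separated), `POP` separators, and one
#' line per individual (`id , a1a2 a1a2 ...`). The all-zero code (`0000` /
#' `000000`) marks a missing genotype. Population labels of the form
#' `<site>_<year>` (taken from the first individual id of each block) become
#' the sample keys; other labels get sequential identifiers. Allele codes
#' are kept numerically as fragment sizes in base pairs.
#'
#' @param path path to a Genepop text file.
#' @param loci optional [locus_table()] carrying repeat units and offsets
#'   (Genepop itself has no metadata slot); names must match the file's.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path, loci = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) abort("not a Genepop file: fewer than 3 lines")
  lines <- sub("\\s+$", "", lines)
  body <- lines[-1L]

  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) abort("not a Genepop file: no POP separator found")

  locus_lines <- body[seq_len(first_pop - 1L)]
  locus_names <- unlist(strsplit(locus_lines, ","), use.names = FALSE)
  locus_names <- trimws(locus_names)
  locus_names <- locus_names[nzchar(locus_names)]
  if (!length(locus_names)) abort("no locus names before the first POP")
  n_loci <- length(locus_names)

  pop_id <- cumsum(is_pop)
  ind_idx <- which(!is_pop & pop_id > 0L & nzchar(trimws(body)))

  rows <- vector("list", length(ind_idx))
  pop_first_id <- character(max(pop_id))
  pop_counter <- integer(max(pop_id))
  width <- NA_integer_

  for (j in seq_along(ind_idx)) {
    i <- ind_idx[j]
    line <- body[i]
    parts <- strsplit(line, ",")[[1L]]
    if (length(parts) < 2L) {
      abort(sprintf("line %d: expected 'id , genotypes' but found no comma", i + 1L))
    }
    id <- trimws(parts[1L])
    cells <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    if (length(cells) != n_loci) {
      abort(sprintf(
        "line %d: %d genotype field(s) but %d loci declared",
        i + 1L, length(cells), n_loci
      ))
    }
    w <- unique(nchar(cells))
    if (length(w) != 1L || !(w %in% c(4L, 6L))) {
      abort(sprintf(
        "line %d: unknown allele-code width (cell widths %s; expected 4 or 6 digits)",
        i + 1L, paste(sort(w), collapse = "/")
      ))
    }
    if (is.na(width)) width <- w / 2L
    if (w / 2L != width) {
      abort(sprintf("line %d: allele-code width changes mid-file", i + 1L))
    }
    a1 <- as.integer(substr(cells, 1L, width))
    a2 <- as.integer(substr(cells, width + 1L, 2L * width))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_

    p <- pop_id[i]
    pop_counter[p] <- pop_counter[p] + 1L
    if (pop_counter[p] == 1L) pop_first_id[p] <- id
    rows[[j]] <- tibble::tibble(
      pop = p,
      individual = sprintf("ind_%03d", pop_counter[p]),
      locus = locus_names,
      allele_1 = a1,
      allele_2 = a2
    )
  }

  geno <- dplyr::bind_rows(rows)
  m <- regmatches(pop_first_id, regexec("^(.+)_([0-9]{4})$", pop_first_id))
  key <- purrr::imap_dfr(m, function(mm, p) {
    if (length(mm) == 3L) {
      tibble::tibble(pop = p, site = mm[2L], year = as.integer(mm[3L]))
    } else {
      tibble::tibble(pop = p, site = sprintf("pop_%02d", p), year = p)
    }
  })
  geno <- dplyr::left_join(geno, key, by = "pop")
  geno$pop <- NULL

  if (is.null(loci)) loci <- locus_table(locus_names)
  genotype_table(geno, loci = loci)
}

#' Write a Genepop file
#'
#' Emits the 3-digit dialect readable by [read_genepop()]: population blocks
#' sorted by site then year, individuals in input order, population labels
#' `<site>_<year>`, missing genotypes coded `000000`.
#'
#' @param geno a [genotype_table()].
#' @param path output path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, path, title = "snaildrift genotype export") {
  lt <- loci(geno)
  sizes <- c(geno$allele_1, geno$allele_2)
  if (any(sizes > 999L, na.rm = TRUE)) {
    abort(paste0(
      "allele sizes > 999 bp cannot be written in the 3-digit Genepop dialect; ",
      "recode alleles to repeat units (subtract the size offset and divide by ",
      "the repeat unit) before writing"
    ))
  }

  keys <- dplyr::arrange(sample_sizes(geno), .data$site, .data$year)
  out <- c(title, lt$locus)
  for (r in seq_len(nrow(keys))) {
    rows <- geno[geno$site == keys$site[r] & geno$year == keys$year[r], ]
    label <- paste0(keys$site[r], "_", keys$year[r])
    out <- c(out, "POP")
    wide <- tidyr::pivot_wider(
      as_plain_tibble(rows),
      id_cols = "individual",
      names_from = "locus",
      values_from = c("allele_1", "allele_2")
    )
    for (i in seq_len(nrow(wide))) {
      cells <- vapply(lt$locus, function(l) {
        a1 <- wide[[paste0("allele_1_", l)]][i]
        a2 <- wide[[paste0("allele_2_", l)]][i]
        if (is.na(a1)) "000000" else sprintf("%03d%03d", a1, a2)
      }, character(1))
      out <- c(out, paste0(label, " ,  ", paste(cells, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write the delimited genotype-table dialect
#'
#' A plain tab-separated table: one row per individual with columns `site`,
#' `year`, `individual`, then two columns per locus (`<locus>_1`,
#' `<locus>_2`). Empty cells are missing genotypes.
#'
#' @param path file path.
#' @param loci optional [locus_table()] (as in [read_genepop()]).
#' @return `read_genotype_table()` returns a [genotype_table()];
#'   `write_genotype_table()` returns `path` invisibly.
#' @export
read_genotype_table <- function(path, loci = NULL) {
  wide <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("site", "year", "individual")
  if (!all(fixed %in% names(wide))) {
    abort("delimited genotype table needs columns site, year, individual")
  }
  locus_cols <- setdiff(names(wide), fixed)
  locus_names <- unique(sub("_[12]$", "", locus_cols))
  long <- tibble::as_tibble(wide) |>
    tidyr::pivot_longer(
      dplyr::all_of(locus_cols),
      names_to = c("locus", ".value"),
      names_pattern = "^(.*)_([12])$"
    ) |>
    dplyr::rename(allele_1 = "1", allele_2 = "2")
  if (is.null(loci)) loci <- locus_table(locus_names)
  genotype_table(long, loci = loci)
}

#' @rdname read_genotype_table
#' @param geno a [genotype_table()].
#' @export
write_genotype_table <- function(geno, path) {
  lt <- loci(geno)
  wide <- tidyr::pivot_wider(
    as_plain_tibble(geno),
    id_cols = c("site", "year", "individual"),
    names_from = "locus",
    values_from = c("allele_1", "allele_2"),
    names_glue = "{locus}_{sub('allele_', '', .value)}"
  )
  ord <- unlist(lapply(lt$locus, function(l) paste0(l, c("_1", "_2"))))
  wide <- wide[c("site", "year", "individual", ord)]
  utils::write.table(wide, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}
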