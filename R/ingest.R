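# Bulk data movement. The tab-delimited section dialect used for import and
# export is: UTF-8, one "### <Section>" header per table, an immediately
# following tab-separated column-name row, then one row per record; lines
# starting with "#" (other than section headers) are comments; empty fields
# are empty strings.

SECTION_TABLES <- c(
  Diseases = "diseases",
  Individuals = "individuals",
  Phenotypes = "phenotypes",
  Screenings = "screenings",
  Screenings_To_Genes = "screenings_genes",
  Screenings_To_Variants = "screenings_variants",
  Variants_On_Genome = "variants_genome",
  Variants_On_Transcripts = "variants_transcript"
)

# Sections matched by a single internal id vs. pure link tables.
SECTION_KEYS <- list(
  Diseases = "id", Individuals = "id", Phenotypes = "id", Screenings = "id",
  Variants_On_Genome = "id",
  Variants_On_Transcripts = c("genomic_variant_id", "transcript_accession"),
  Screenings_To_Genes = NULL, Screenings_To_Variants = NULL
)

format_cell <- function(x) {
  if (is.logical(x)) {
    ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
  } else {
    ifelse(is.na(x), "", as.character(x))
  }
}

#' Export database tables as a tab-delimited section file
#'
#' @param db An [lovd_instance()].
#' @param sections Section names to export (default: all).
#' @return A single string in the section dialect.
#' @export
export_sections <- function(db, sections = names(SECTION_TABLES)) {
  bad <- setdiff(sections, names(SECTION_TABLES))
  if (length(bad)) {
    abort_validation(sprintf("Unknown section(s): %s.", paste(bad, collapse = ", ")))
  }
  out <- character()
  for (s in sections) {
    tbl <- db[[SECTION_TABLES[[s]]]]
    out <- c(out, paste0("### ", s),
             paste(names(tbl), collapse = "\t"))
    if (nrow(tbl)) {
      rows <- apply(as.data.frame(lapply(tbl, format_cell)), 1,
                    paste, collapse = "\t")
      out <- c(out, rows)
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

parse_section_file <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sections <- list()
  current <- NULL
  header <- NULL
  rows <- list()
  flush <- function() {
    if (!is.null(current)) {
      body <- if (length(rows)) {
        m <- do.call(rbind, lapply(rows, function(r) {
          f <- strsplit(r, "\t", fixed = TRUE)[[1]]
          length(f) <- length(header)  # pad rows whose trailing fields are empty
          f[is.na(f)] <- ""
          f
        }))
        tbl <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE),
                         .name_repair = "minimal")
        names(tbl) <- header
        tbl
      } else {
        as_tibble(setNames(rep(list(character()), length(header)), header))
      }
      sections[[current]] <<- body
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^### ", ln)) {
      flush()
      current <- sub("^### ", "", ln)
      header <- NULL
      rows <- list()
    } else if (grepl("^#", ln) || !nzchar(trimws(ln))) {
      next
    } else if (is.null(current)) {
      abort_validation(sprintf("Line %d appears before any section header.", i))
    } else if (is.null(header)) {
      header <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    } else {
      rows <- c(rows, ln)
    }
  }
  flush()
  if (length(sections) == 0) {
    abort_validation("No '### <Section>' headers found in the file.")
  }
  bad <- setdiff(names(sections), names(SECTION_TABLES))
  if (length(bad)) {
    abort_validation(sprintf("Malformed/unknown section header(s): %s.",
                             paste(bad, collapse = ", ")))
  }
  sections
}

coerce_like <- function(value, template) {
  if (is.integer(template)) as.integer(value)
  else if (is.double(template)) as.double(value)
  else if (is.logical(template)) as.logical(value)
  else ifelse(value == "", NA_character_, value)
}

new_import_report <- function(mode) {
  structure(
    list(mode = mode, accepted = 0L, rejected = 0L, fatal = FALSE,
         messages = tibble(section = character(), entry = character(),
                           message = character())),
    class = "import_report"
  )
}

report_msg <- function(rep, section, entry, message) {
  rep$messages <- bind_rows(rep$messages, tibble(
    section = section, entry = as.character(entry), message = message
  ))
  rep
}

#' @export
print.import_report <- function(x, ...) {
  cat(sprintf("<import_report> mode=%s accepted=%d rejected=%d%s\n",
              x$mode, x$accepted, x$rejected,
              if (x$fatal) " FATAL (nothing applied)" else ""))
  if (nrow(x$messages)) print(x$messages)
  invisible(x)
}

#' Import a tab-delimited section file
#'
#' In `update` mode entries are matched to database rows by their internal
#' ids and field-level diffs are computed; at most one changed field per entry
#' is permitted (a guard against replacing whole entries after a mistyped id).
#' Any entry with two or more changes — or an unknown id, or a malformed
#' section — makes the whole file fatal and nothing is applied. `insert` mode
#' appends new rows; `simulate` validates either way without writing.
#'
#' @param db An [lovd_instance()].
#' @param file Path to a section file, or the file's text (anything containing
#'   a newline is treated as text).
#' @param mode `"update"`, `"insert"` or `"simulate"` (simulated update).
#' @return An `import_report`; `fatal = TRUE` implies zero rows written.
#' @export
import_update_file <- function(db, file, mode = c("update", "insert", "simulate")) {
  mode <- arg_match(mode)
  if (mode != "simulate") check_mutable(db)
  text <- if (grepl("\n", file, fixed = TRUE)) file else {
    paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  rep <- new_import_report(mode)
  sections <- tryCatch(parse_section_file(text), varlocus_validation_error = function(e) e)
  if (inherits(sections, "error")) {
    rep$fatal <- TRUE
    return(report_msg(rep, "<file>", NA, conditionMessage(sections)))
  }
  snapshot <- db_snapshot(db)
  # First pass: validate and stage every change; apply only if nothing fatal.
  staged <- list()
  for (s in names(sections)) {
    incoming <- sections[[s]]
    tbl_name <- SECTION_TABLES[[s]]
    current <- db[[tbl_name]]
    keys <- SECTION_KEYS[[s]]
    unknown_cols <- setdiff(names(incoming), names(current))
    if (length(unknown_cols)) {
      rep$fatal <- TRUE
      rep <- report_msg(rep, s, NA, sprintf(
        "Unknown column(s): %s.", paste(unknown_cols, collapse = ", ")))
      next
    }
    if (mode == "insert") {
      staged[[length(staged) + 1]] <- list(kind = "insert", section = s,
                                           table = tbl_name, rows = incoming)
      rep$accepted <- rep$accepted + nrow(incoming)
      next
    }
    if (is.null(keys)) {
      # Link tables carry no internal id; they must match the database exactly.
      cur_rows <- apply(as.data.frame(lapply(current[names(incoming)], format_cell)),
                        1, paste, collapse = "\t")
      inc_rows <- apply(as.data.frame(incoming), 1, paste, collapse = "\t")
      if (!setequal(cur_rows, inc_rows)) {
        rep$fatal <- TRUE
        rep <- report_msg(rep, s, NA,
                          "Link sections can not be changed through an update import.")
      }
      next
    }
    if (!all(keys %in% names(incoming))) {
      rep$fatal <- TRUE
      rep <- report_msg(rep, s, NA, sprintf(
        "Section is missing its key column(s): %s.", paste(keys, collapse = ", ")))
      next
    }
    for (r in seq_len(nrow(incoming))) {
      entry <- incoming[r, ]
      entry_key <- paste(unlist(entry[keys]), collapse = "/")
      hit <- rep(TRUE, nrow(current))
      for (k in keys) hit <- hit & format_cell(current[[k]]) == entry[[k]]
      if (sum(hit) != 1) {
        rep$fatal <- TRUE
        rep <- report_msg(rep, s, entry_key, "Unknown internal id.")
        next
      }
      i <- which(hit)
      changed <- character()
      for (col in setdiff(names(entry), keys)) {
        if (format_cell(current[[col]][i]) != entry[[col]]) changed <- c(changed, col)
      }
      if (length(changed) >= 2) {
        rep$fatal <- TRUE
        rep <- report_msg(rep, s, entry_key, sprintf(
          "More than one change detected (%s); the entire file is rejected.",
          paste(changed, collapse = ", ")))
      } else if (length(changed) == 1) {
        staged[[length(staged) + 1]] <- list(
          kind = "update", section = s, table = tbl_name, row = i,
          column = changed, value = entry[[changed]]
        )
        rep$accepted <- rep$accepted + 1L
      }
    }
  }
  if (rep$fatal) {
    rep$rejected <- rep$accepted + rep$rejected
    rep$accepted <- 0L
    db_restore(db, snapshot)
    return(rep)
  }
  if (mode == "simulate") return(rep)
  for (ch in staged) {
    if (ch$kind == "insert") {
      tbl <- db[[ch$table]]
      rows <- ch$rows
      for (col in names(rows)) rows[[col]] <- coerce_like(rows[[col]], tbl[[col]])
      db[[ch$table]] <- bind_rows(tbl, rows)
    } else {
      db[[ch$table]][[ch$column]][ch$row] <-
        coerce_like(ch$value, db[[ch$table]][[ch$column]])
    }
  }
  rep
}

#' Find and replace over one column of one table
#'
#' Substring (fixed, not regex) replacement. Preview mode reports the affected
#' row count without writing. Managers may edit any table; curators only rows
#' linked to genes in their care. A replacement that would empty a mandatory
#' field is refused.
#'
#' @param db An [lovd_instance()].
#' @param entity `"variant"`, `"individual"`, `"phenotype"` or `"screening"`.
#' @param column Physical column name or custom-column id.
#' @param needle,replacement Fixed strings.
#' @param preview If `TRUE` (default) nothing is written.
#' @param actor Acting user id; `NULL` skips the rights check (internal use).
#' @return List with `affected` (row count) and `written`.
#' @export
find_and_replace <- function(db, entity = c("variant", "individual",
                                            "phenotype", "screening"),
                             column, needle, replacement,
                             preview = TRUE, actor = NULL) {
  entity <- arg_match(entity)
  if (!preview) check_mutable(db)
  tbl_name <- c(variant = "variants_genome", individual = "individuals",
                phenotype = "phenotypes", screening = "screenings")[[entity]]
  phys <- physical_name(column)
  tbl <- db[[tbl_name]]
  if (!phys %in% names(tbl)) {
    abort_validation(sprintf("No column '%s' on %s records.", column, entity))
  }
  vals <- tbl[[phys]]
  hit <- !is.na(vals) & grepl(needle, vals, fixed = TRUE)
  if (!is.null(actor)) {
    u <- get_user(db, actor)
    if (is.null(u)) abort_authorization("Unknown user.")
    if (!u$role_global %in% c("admin", "manager")) {
      curated <- u$curated_genes[[1]]
      if (length(curated) == 0) {
        abort_authorization("Find-and-replace requires curator or manager rights.")
      }
      kind <- entity
      ok <- map_lgl(tbl$id[hit], function(i) {
        facts <- record_facts(db, kind, i)
        length(facts$genes) > 0 && all(facts$genes %in% curated)
      })
      if (!all(ok)) {
        abort_authorization(
          "Curators may only edit records linked to the genes in their care."
        )
      }
    }
  }
  new_vals <- vals
  new_vals[hit] <- gsub(needle, replacement, vals[hit], fixed = TRUE)
  mand <- db$columns$mandatory[map_chr(db$columns$column_id, physical_name) == phys]
  if (length(mand) && any(mand) && any(hit & !nzchar(new_vals))) {
    abort_validation(sprintf(
      "Replacement would empty the mandatory field '%s'; refused.", column
    ))
  }
  if (!preview) db[[tbl_name]][[phys]] <- new_vals
  list(affected = sum(hit), written = !preview)
}

# ---- VCF in ----------------------------------------------------------------

# Trim the shared prefix/suffix of a VCF REF/ALT pair and express the change
# as HGVS g. nomenclature. With sequence available, deletions/duplications/
# insertions are 3'-shifted per the HGVS convention; without it, positions
# pass through flagged unnormalized.
vcf_allele_to_hgvs <- function(pos, ref, alt, sequence = NULL, seq_start = 1L) {
  pos <- as.integer(pos)
  # common prefix
  npre <- 0L
  while (npre < nchar(ref) && npre < nchar(alt) &&
         substr(ref, npre + 1, npre + 1) == substr(alt, npre + 1, npre + 1)) {
    npre <- npre + 1L
  }
  r <- substr(ref, npre + 1, nchar(ref))
  a <- substr(alt, npre + 1, nchar(alt))
  # common suffix
  nsuf <- 0L
  while (nsuf < nchar(r) && nsuf < nchar(a) &&
         substr(r, nchar(r) - nsuf, nchar(r) - nsuf) ==
         substr(a, nchar(a) - nsuf, nchar(a) - nsuf)) {
    nsuf <- nsuf + 1L
  }
  r <- substr(r, 1, nchar(r) - nsuf)
  a <- substr(a, 1, nchar(a) - nsuf)
  start <- pos + npre
  at <- function(p) substr(sequence, p - seq_start + 1, p - seq_start + 1)
  normalized <- !is.null(sequence)

  if (nchar(r) == 1 && nchar(a) == 1) {
    return(list(description = sprintf("g.%d%s>%s", start, r, a), normalized = TRUE))
  }
  if (nchar(a) == 0 && nchar(r) > 0) {            # deletion
    end <- start + nchar(r) - 1L
    if (!is.null(sequence)) {
      while (nzchar(at(end + 1L)) && at(end + 1L) == at(start)) {
        start <- start + 1L
        end <- end + 1L
      }
    }
    desc <- if (start == end) sprintf("g.%ddel", start) else
      sprintf("g.%d_%ddel", start, end)
    return(list(description = desc, normalized = normalized))
  }
  if (nchar(r) == 0 && nchar(a) > 0) {            # insertion (after start - 1)
    site <- start - 1L   # inserted between site and site + 1
    ins <- a
    if (!is.null(sequence)) {
      repeat {                                     # 3'-shift by rotation
        nxt <- at(site + 1L)
        if (!nzchar(nxt) || nxt != substr(ins, 1, 1)) break
        ins <- paste0(substr(ins, 2, nchar(ins)), substr(ins, 1, 1))
        site <- site + 1L
      }
      k <- nchar(ins)
      if (site - k + 1L >= seq_start &&
          substr(sequence, site - k + 1L - seq_start + 1L, site - seq_start + 1L) == ins) {
        desc <- if (k == 1) sprintf("g.%ddup", site) else
          sprintf("g.%d_%ddup", site - k + 1L, site)
        return(list(description = desc, normalized = TRUE))
      }
    }
    return(list(description = sprintf("g.%d_%dins%s", site, site + 1L, ins),
                normalized = normalized))
  }
  end <- start + nchar(r) - 1L
  desc <- if (start == end) sprintf("g.%ddelins%s", start, a) else
    sprintf("g.%d_%ddelins%s", start, end, a)
  list(description = desc, normalized = normalized)
}

#' Import variant drafts from a VCF file
#'
#' Each ALT allele becomes one draft genomic variant; multi-allelic sites are
#' split. VCF's anchored-base alleles are converted to HGVS `g.` descriptions;
#' when `sequence` is supplied, indels are 3'-shifted and insertions matching
#' the preceding sequence are written as duplications. Malformed lines are
#' reported per line and the import continues.
#'
#' @param db An [lovd_instance()]; the declared build must match the instance.
#' @param path Path to a VCF 4.x file.
#' @param genome_build Build the VCF coordinates refer to.
#' @param sequence Optional reference sequence for normalization (toy loci).
#' @param seq_start Genomic position of `sequence`'s first base.
#' @return Tibble of drafts: `chromosome`, `position`, `ref`, `alt`,
#'   `dna_description`, `normalized`, `message` (`NA` unless skipped).
#' @export
import_vcf <- function(db, path, genome_build, sequence = NULL, seq_start = 1L) {
  if (!identical(genome_build, db$settings$genome_build)) {
    abort_validation(sprintf(
      "Genome build mismatch: instance uses %s, VCF declares %s.",
      db$settings$genome_build, genome_build
    ))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  drafts <- list()
  for (i in seq_len(nrow(fix))) {
    chrom <- sub("^chr", "", fix$CHROM[i])
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i] %||% ".", ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (is.na(alt) || alt %in% c(".", "")) {
        drafts[[length(drafts) + 1]] <- tibble(
          chromosome = chrom, position = pos, ref = ref, alt = alt,
          dna_description = NA_character_, normalized = NA,
          message = "No alternate allele; line skipped."
        )
        next
      }
      if (is.na(pos) || !grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]+$", alt)) {
        drafts[[length(drafts) + 1]] <- tibble(
          chromosome = chrom, position = pos, ref = ref, alt = alt,
          dna_description = NA_character_, normalized = NA,
          message = "Malformed record; line skipped."
        )
        next
      }
      h <- vcf_allele_to_hgvs(pos, ref, alt, sequence, seq_start)
      drafts[[length(drafts) + 1]] <- tibble(
        chromosome = chrom, position = pos, ref = ref, alt = alt,
        dna_description = h$description, normalized = h$normalized,
        message = NA_character_
      )
    }
  }
  bind_rows(drafts)
}

# ---- BED out ---------------------------------------------------------------

#' Export variants as a BED track
#'
#' One line per unique variant description (observations are grouped), with
#' the model's 1-based inclusive spans converted to BED's 0-based half-open
#' convention. An empty set yields a header-only file.
#'
#' @param variants Tibble with `chromosome`, `position_start`, `position_end`,
#'   `dna_description` (e.g. from [query_records()]).
#' @param track_name Track header name.
#' @return BED text as a single string.
#' @export
export_bed <- function(variants, track_name = "varlocus") {
  header <- sprintf('track name="%s" description="variant track"', track_name)
  if (nrow(variants) == 0) return(paste0(header, "\n"))
  u <- distinct(variants, .data$dna_description, .keep_all = TRUE)
  lines <- sprintf("chr%s\t%d\t%d\t%s",
                   u$chromosome,
                   as.integer(u$position_start) - 1L,
                   as.integer(u$position_end),
                   u$dna_description)
  paste0(paste(c(header, lines), collapse = "\n"), "\n")
}

# ---- legacy conversion -----------------------------------------------------

#' Convert legacy single-table rows to the eight-table layout
#'
#' Legacy gene databases stored one flat row per variant observation with the
#' patient, screening and variant fields side by side. This splits such rows
#' into the full-submission layout, deduplicating individuals by their patient
#' id. Expected columns: `patientid`, `gene`, `transcript`, `cdna`,
#' `genomic_dna`, `chromosome`; optional: `technique`, `disease`, `reference`.
#'
#' @param flat_rows Data frame of legacy rows.
#' @return List of tibbles `individuals`, `phenotypes`, `screenings`,
#'   `screenings_genes`, `screenings_variants`, `variants_genome`,
#'   `variants_transcript`, `diseases`, plus `errors` (row-level problems).
#' @export
convert_legacy_rows <- function(flat_rows) {
  flat_rows <- as_tibble(flat_rows)
  need <- c("patientid", "gene", "transcript", "cdna", "genomic_dna", "chromosome")
  missing_cols <- setdiff(need, names(flat_rows))
  if (length(missing_cols)) {
    abort_validation(sprintf("Legacy rows are missing column(s): %s.",
                             paste(missing_cols, collapse = ", ")))
  }
  opt <- function(col) {
    if (col %in% names(flat_rows)) flat_rows[[col]] else rep(NA_character_, nrow(flat_rows))
  }
  technique <- opt("technique"); disease <- opt("disease"); reference <- opt("reference")

  errors <- tibble(row = integer(), message = character())
  ok <- rep(TRUE, nrow(flat_rows))
  for (i in seq_len(nrow(flat_rows))) {
    if (is.na(flat_rows$patientid[i]) || !nzchar(flat_rows$patientid[i])) {
      errors <- bind_rows(errors, tibble(row = i, message = "Missing patient id."))
      ok[i] <- FALSE
    } else if ((is.na(flat_rows$cdna[i]) || !nzchar(flat_rows$cdna[i])) &&
               (is.na(flat_rows$genomic_dna[i]) || !nzchar(flat_rows$genomic_dna[i]))) {
      errors <- bind_rows(errors, tibble(row = i, message = "Missing DNA field."))
      ok[i] <- FALSE
    }
  }
  rows <- flat_rows[ok, ]
  technique <- technique[ok]; disease <- disease[ok]; reference <- reference[ok]

  pids <- unique(rows$patientid)
  individuals <- tibble(
    id = seq_along(pids), legacy_patientid = pids,
    visibility = "non_public", owner_id = NA_integer_,
    reference = reference[match(pids, rows$patientid)]
  )
  ind_of <- function(pid) individuals$id[match(pid, individuals$legacy_patientid)]

  dnames <- unique(disease[!is.na(disease)])
  diseases <- tibble(id = seq_along(dnames), name = dnames,
                     omim_id = NA_integer_)
  phenotypes <- tibble(
    id = integer(), individual_id = integer(), disease_id = integer(),
    observation_date = character()
  )
  if (length(dnames)) {
    pairs <- distinct(tibble(pid = rows$patientid, dis = disease))
    pairs <- pairs[!is.na(pairs$dis), ]
    phenotypes <- tibble(
      id = seq_len(nrow(pairs)),
      individual_id = map_int(pairs$pid, ind_of),
      disease_id = match(pairs$dis, dnames),
      observation_date = NA_character_
    )
  }
  n <- nrow(rows)
  screenings <- tibble(
    id = seq_len(n),
    individual_id = map_int(rows$patientid, ind_of),
    technique = technique, variants_found = TRUE
  )
  screenings_genes <- tibble(screening_id = seq_len(n), gene_symbol = rows$gene)
  variants_genome <- tibble(
    id = seq_len(n), chromosome = rows$chromosome,
    dna_description = rows$genomic_dna, visibility = "non_public",
    reference = reference
  )
  variants_transcript <- tibble(
    genomic_variant_id = seq_len(n),
    transcript_accession = rows$transcript,
    cdna_description = rows$cdna, rna_description = "r.(?)",
    protein_description = NA_character_,
    effect_reported = "unknown", effect_concluded = "unknown"
  )
  screenings_variants <- tibble(screening_id = seq_len(n), variant_id = seq_len(n))

  list(
    individuals = individuals, phenotypes = phenotypes,
    screenings = screenings, screenings_genes = screenings_genes,
    screenings_variants = screenings_variants,
    variants_genome = variants_genome,
    variants_transcript = variants_transcript,
    diseases = diseases, errors = errors
  )
}
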