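# The three service surfaces, modelled as plain functions over request
# objects: gene-based data retrieval, validated queued submission, and the
# federated cross-instance search. Responses are JSON-serializable lists with
# tibble payloads; only public records are served unless the request carries a
# token with view rights.

SUPPORTED_API_VERSIONS <- "v1"

check_api_version <- function(version) {
  if (!version %in% SUPPORTED_API_VERSIONS) {
    abort(sprintf(
      "Unsupported API version '%s' (supported: %s).",
      version, paste(SUPPORTED_API_VERSIONS, collapse = ", ")
    ), class = "varlocus_version_error")
  }
  invisible(version)
}

# Transcript of a gene with the most variants annotated (the default for
# gene-based listings); ties break alphabetically for determinism.
default_transcript <- function(db, gene_symbol) {
  txs <- list_transcripts(db, gene_symbol)
  if (nrow(txs) == 0) return(NA_character_)
  counts <- map_int(txs$accession, function(a) {
    sum(db$variants_transcript$transcript_accession == a)
  })
  txs$accession[order(-counts, txs$accession)][1]
}

gene_locus_span <- function(db, gene_symbol) {
  txs <- keep(db$transcripts, function(t) t$gene_symbol == gene_symbol)
  if (length(txs) == 0) return(c(NA_real_, NA_real_))
  spans <- map(txs, locus_span)
  c(min(map_dbl(spans, 1)), max(map_dbl(spans, 2)))
}

#' Handle a data-retrieval request
#'
#' Gene listings can be searched by symbol, chromosome or chromosomal
#' position; variant listings are gene-based, showing every observation or
#' grouping observations by unique variant description with an observation
#' count, and can additionally be narrowed by genomic position/range, DNA
#' description or DBID. Without a token only public records are served;
#' grouped and ungrouped rows carry the genomic location, owner, creator and
#' timestamps.
#'
#' @param db An [lovd_instance()].
#' @param request Named list. Common keys: `resource` (`"genes"` or
#'   `"variants"`), `api_version` (default `"v1"`), `token`. For genes:
#'   `symbol`, `chromosome`, `position`. For variants: `gene` (required),
#'   `group` (flag), `position`, `range`, `dna_description`, `dbid`.
#' @return List with `status`, `resource`, `data` (tibble), `warnings`.
#' @export
handle_retrieval <- function(db, request) {
  check_api_version(request$api_version %||% "v1")
  resource <- request$resource %||% "variants"
  viewer <- NULL
  if (!is.null(request$token)) {
    u <- user_by_token(db, request$token)
    if (is.null(u)) {
      abort("Unknown API token.", class = "varlocus_authentication_error")
    }
    viewer <- u$id
  }
  warnings <- character()

  if (resource == "genes") {
    g <- db$genes
    if (!is.null(request$symbol)) g <- g[g$symbol == request$symbol, ]
    if (!is.null(request$chromosome)) g <- g[g$chromosome == request$chromosome, ]
    if (!is.null(request$position)) {
      pos <- as.numeric(request$position)
      if (is.na(pos)) abort_validation("position must be numeric.")
      covers <- map_lgl(g$symbol, function(s) {
        span <- gene_locus_span(db, s)
        !is.na(span[1]) && pos >= span[1] && pos <= span[2]
      })
      g <- g[covers, ]
    }
    if (nrow(g)) {
      spans <- map(g$symbol, gene_locus_span, db = db)
      g <- mutate(g,
                  locus_start = map_dbl(spans, 1),
                  locus_end = map_dbl(spans, 2),
                  default_transcript = map_chr(.data$symbol, default_transcript, db = db))
    }
    return(list(status = "ok", resource = "genes", data = g, warnings = warnings))
  }

  if (resource != "variants") {
    abort_validation(sprintf("Unknown resource '%s'.", resource))
  }
  filters <- list()
  if (!is.null(request$gene)) {
    if (!request$gene %in% db$genes$symbol) {
      return(list(status = "ok", resource = "variants",
                  data = db$variants_genome[0, ],
                  warnings = sprintf("Unknown gene '%s'.", request$gene)))
    }
    filters$gene <- request$gene
  }
  if (!is.null(request$range)) {
    r <- suppressWarnings(as.numeric(request$range))
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2]) {
      abort_validation("range must be two numbers with start <= end.")
    }
    filters$range <- r
    filters$chromosome <- request$chromosome %||%
      if (!is.null(filters$gene)) db$genes$chromosome[db$genes$symbol == filters$gene] else
        abort_validation("Range queries need a chromosome or gene.")
  } else if (!is.null(request$position)) {
    pos <- suppressWarnings(as.numeric(request$position))
    if (is.na(pos)) abort_validation("position must be numeric.")
    filters$range <- c(pos, pos)
    filters$chromosome <- request$chromosome %||%
      if (!is.null(filters$gene)) db$genes$chromosome[db$genes$symbol == filters$gene] else
        abort_validation("Position queries need a chromosome or gene.")
  }
  if (!is.null(request$dbid)) filters$dbid <- request$dbid
  if (!is.null(request$dna_description)) filters$dna_description <- request$dna_description
  v <- query_records(db, "variant", filters = filters, viewer = viewer,
                     page_size = .Machine$integer.max)
  tx_acc <- if (!is.null(filters$gene)) default_transcript(db, filters$gene) else NA_character_
  if (!is.na(tx_acc)) {
    ann <- db$variants_transcript[db$variants_transcript$transcript_accession == tx_acc,
                                  c("genomic_variant_id", "cdna_description",
                                    "effect_concluded")]
    names(ann) <- c("id", "cdna_description", "transcript_effect")
    v <- left_join(v, ann, by = "id")
    v$default_transcript <- tx_acc
  }
  if (isTRUE(request$group)) {
    v <- v |>
      group_by(.data$dna_description) |>
      summarise(
        chromosome = .data$chromosome[1],
        position_start = .data$position_start[1],
        position_end = .data$position_end[1],
        dbid = .data$dbid[1],
        observation_count = n(),
        .groups = "drop"
      )
  }
  list(status = "ok", resource = "variants", data = v, warnings = warnings)
}

# ---- submission ------------------------------------------------------------

#' Validate (and queue) a case-level submission document
#'
#' Documents follow the case hierarchy: an `individual` with optional
#' `phenotypes` and `screenings`, and `variants` (each with optional
#' per-transcript annotations). Full submissions must include the individual;
#' variant-only documents are accepted only from accounts authorized for them.
#' Every missing mandatory field and invalid value is reported with its path.
#' Valid documents are queued for import, not written.
#'
#' @param db An [lovd_instance()].
#' @param document Nested list (parse JSON with [jsonlite::fromJSON] using
#'   `simplifyVector = FALSE`).
#' @param token Submitter's API token.
#' @param api_version Version the client speaks.
#' @return List: `valid`, `errors` (tibble `path`, `message`), and on success
#'   `status = "queued"` with `queue_id`.
#' @export
validate_submission <- function(db, document, token, api_version = "v1") {
  check_api_version(api_version)
  account <- user_by_token(db, token)
  if (is.null(account)) {
    abort("Unknown API token.", class = "varlocus_authentication_error")
  }
  errors <- tibble(path = character(), message = character())
  err <- function(path, message) {
    errors <<- bind_rows(errors, tibble(path = path, message = message))
  }
  if (is.null(document$individual)) {
    if (!isTRUE(account$variant_only)) {
      err("individual",
          paste("Full submissions must include information on the individual;",
                "this account is not authorized for variant-only submissions."))
    }
  }
  phenos <- document$individual$phenotypes %||% list()
  for (i in seq_along(phenos)) {
    ph <- phenos[[i]]
    path <- sprintf("individual.phenotypes[%d]", i)
    if (is.null(ph$disease_id)) {
      err(paste0(path, ".disease_id"), "Missing mandatory field.")
    } else if (!ph$disease_id %in% db$diseases$id) {
      err(paste0(path, ".disease_id"), "Unknown disease.")
    }
    if (is.null(ph$observation_date)) {
      err(paste0(path, ".observation_date"), "Missing mandatory field.")
    }
  }
  variants <- document$variants %||% list()
  if (length(variants) == 0) err("variants", "A submission must contain at least one variant.")
  for (i in seq_along(variants)) {
    va <- variants[[i]]
    path <- sprintf("variants[%d]", i)
    if (is.null(va$dna_description) || !nzchar(va$dna_description)) {
      err(paste0(path, ".dna_description"), "Missing mandatory field.")
    } else {
      pv <- tryCatch(parse_description(va$dna_description),
                     varlocus_parse_error = function(e) e)
      if (inherits(pv, "error")) {
        err(paste0(path, ".dna_description"), conditionMessage(pv))
      } else if (pv$level != "g") {
        err(paste0(path, ".dna_description"), "Genomic records need a g. description.")
      }
    }
    if (is.null(va$chromosome) || !va$chromosome %in% ALLOWED_CHROMOSOMES) {
      err(paste0(path, ".chromosome"), "Missing or invalid chromosome.")
    }
    for (fld in c("effect_reported", "effect_concluded")) {
      if (!is.null(va[[fld]]) && !va[[fld]] %in% EFFECT_CLASSES) {
        err(paste0(path, ".", fld), sprintf(
          "Value '%s' is outside the effect enumeration.", va[[fld]]))
      }
    }
    anns <- va$transcripts %||% list()
    for (j in seq_along(anns)) {
      an <- anns[[j]]
      tpath <- sprintf("%s.transcripts[%d]", path, j)
      if (is.null(an$accession) || !an$accession %in% names(db$transcripts)) {
        err(paste0(tpath, ".accession"), "Unknown transcript accession.")
      }
      if (!is.null(an$effect_reported) && !an$effect_reported %in% EFFECT_CLASSES) {
        err(paste0(tpath, ".effect_reported"), sprintf(
          "Value '%s' is outside the effect enumeration.", an$effect_reported))
      }
    }
  }
  if (nrow(errors)) {
    return(list(valid = FALSE, status = "rejected", errors = errors,
                api_version = api_version))
  }
  qid <- next_id(db, "queue")
  db$queue[[as.character(qid)]] <- list(
    id = qid, document = document, account_id = account$id, status = "queued"
  )
  list(valid = TRUE, status = "queued", queue_id = qid,
       errors = errors, api_version = api_version)
}

#' Process the submission queue
#'
#' By default a queued document is imported only when its account is flagged
#' `auto_import` (otherwise it waits for a manager-triggered pass). Imported
#' records are non-public unless the account is flagged `auto_publish`. A
#' document failing mid-import is marked failed; other documents are
#' unaffected.
#'
#' @param db An [lovd_instance()].
#' @param manager_trigger Set by a manager to process documents from accounts
#'   without `auto_import`.
#' @return Tibble: `queue_id`, `status`, `n_variants`, `message`.
#' @export
process_queue <- function(db, manager_trigger = FALSE) {
  check_mutable(db)
  out <- list()
  for (key in names(db$queue)) {
    item <- db$queue[[key]]
    if (item$status != "queued") next
    account <- get_user(db, item$account_id)
    if (!isTRUE(account$auto_import) && !manager_trigger) {
      out[[key]] <- tibble(queue_id = item$id, status = "queued",
                           n_variants = NA_integer_,
                           message = "Awaiting manager-triggered import.")
      next
    }
    visibility <- if (isTRUE(account$auto_publish)) "public" else "non_public"
    snapshot <- db_snapshot(db)
    res <- tryCatch({
      doc <- item$document
      n_var <- 0L
      ind_id <- NA_integer_
      scr_id <- NA_integer_
      if (!is.null(doc$individual)) {
        ind <- add_individual(db, visibility = visibility,
                              owner_id = account$id,
                              reference = doc$individual$reference %||% NA_character_)
        ind_id <- ind$id
        for (ph in doc$individual$phenotypes %||% list()) {
          add_phenotype(db, ind_id, ph$disease_id, ph$observation_date)
        }
        scr <- add_screening(db, ind_id,
                             technique = doc$individual$technique %||% NA_character_,
                             genes_screened = character(),
                             variants_found = length(doc$variants %||% list()) > 0)
        scr_id <- scr$id
      }
      for (va in doc$variants %||% list()) {
        obs <- create_variant_observation(
          db, dna_description = va$dna_description,
          chromosome = va$chromosome,
          effect_reported = va$effect_reported %||% "unknown",
          visibility = visibility, owner_id = account$id,
          transcripts = va$transcripts %||% list()
        )
        n_var <- n_var + 1L
        if (!is.na(scr_id)) link_screening_variant(db, scr_id, obs$variant$id)
      }
      db$queue[[key]]$status <- "imported"
      tibble(queue_id = item$id, status = "imported",
             n_variants = n_var, message = NA_character_)
    }, error = function(e) {
      db_restore(db, snapshot)
      db$queue[[key]]$status <- "failed"
      tibble(queue_id = item$id, status = "failed",
             n_variants = 0L, message = conditionMessage(e))
    })
    out[[key]] <- res
  }
  if (length(out)) bind_rows(out) else {
    tibble(queue_id = integer(), status = character(),
           n_variants = integer(), message = character())
  }
}

# ---- federated query -------------------------------------------------------

#' Build a federated instance registry
#'
#' @param ... Entries created by [federated_instance()].
#' @return A list of class `federated_registry`.
#' @export
federated_registry <- function(...) {
  structure(list(...), class = "federated_registry")
}

#' @rdname federated_registry
#' @param url Base URL identifying the instance in hit links.
#' @param db The instance's [lovd_instance()], or `NULL` for an unreachable
#'   instance.
#' @param listed Whether the instance opted into the global listing; unlisted
#'   instances are excluded from the fan-out.
#' @export
federated_instance <- function(url, db, listed = TRUE) {
  list(url = url, db = db, listed = listed)
}

#' Query every registered instance for a variant
#'
#' Fans out a genomic position/range search (optionally restricted to a gene
#' symbol) to each instance that opted into the listing, aggregates public
#' hits, and reports unreachable instances as warnings rather than failures.
#' Hit sets are independent of registry order.
#'
#' @param registry A [federated_registry()].
#' @param chromosome Chromosome to search.
#' @param position Single genomic position (or use `range`).
#' @param range Two-element genomic range.
#' @param gene Optional gene symbol filter.
#' @return List with `hits` (tibble: `instance_url`, `gene_symbol`,
#'   `dna_description`, `effect`, `record_link`), `warnings`, `notice`.
#' @export
federated_query <- function(registry, chromosome, position = NULL,
                            range = NULL, gene = NULL) {
  stopifnot(inherits(registry, "federated_registry"))
  if (is.null(range)) {
    if (is.null(position)) abort_validation("Provide a position or a range.")
    range <- c(position, position)
  }
  active <- keep(registry, function(e) isTRUE(e$listed))
  if (length(active) == 0) {
    return(list(hits = empty_hits(), warnings = character(),
                notice = "No instances registered for the global listing."))
  }
  warnings <- character()
  hits <- list()
  for (e in active) {
    if (is.null(e$db)) {
      warnings <- c(warnings, sprintf("Instance %s is unreachable.", e$url))
      next
    }
    v <- query_records(e$db, "variant",
                       filters = list(chromosome = chromosome,
                                      range = range, gene = gene),
                       viewer = NULL, page_size = .Machine$integer.max)
    if (nrow(v) == 0) next
    hits[[e$url]] <- tibble(
      instance_url = e$url,
      gene_symbol = map_chr(v$id, function(i) {
        g <- variant_genes(e$db, i)
        if (length(g)) g[1] else NA_character_
      }),
      dna_description = v$dna_description,
      effect = ifelse(v$effect_concluded != "unknown",
                      v$effect_concluded, v$effect_reported),
      record_link = sprintf("%s/variants/%d", e$url, v$id)
    )
  }
  list(
    hits = if (length(hits)) bind_rows(hits) else empty_hits(),
    warnings = warnings, notice = NULL
  )
}

empty_hits <- function() {
  tibble(instance_url = character(), gene_symbol = character(),
         dna_description = character(), effect = character(),
         record_link = character())
}
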