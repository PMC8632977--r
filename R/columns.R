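# Custom columns are realized as physical relational columns on the backing
# tables (not entity-attribute-value rows): activating a column for the first
# time adds a real column to the scope's table, deactivating its last target
# drops it. Core columns map onto built-in physical fields and can never be
# deactivated or removed.

COLUMN_SCOPES <- c("individual", "phenotype", "screening",
                   "variant_genome", "variant_transcript")

COLUMN_DATATYPES <- c("text", "integer", "decimal", "date", "select")

SCOPE_TABLE <- c(
  individual = "individuals", phenotype = "phenotypes",
  screening = "screenings", variant_genome = "variants_genome",
  variant_transcript = "variants_transcript"
)

SCOPE_PREFIX <- c(
  individual = "Individual", phenotype = "Phenotype", screening = "Screening",
  variant_genome = "VariantOnGenome", variant_transcript = "VariantOnTranscript"
)

# Core columns are stored in built-in physical fields.
CORE_PHYSICAL <- c(
  "VariantOnGenome/DNA" = "dna_description",
  "VariantOnTranscript/DNA" = "cdna_description",
  "VariantOnTranscript/RNA" = "rna_description"
)

core_column_registry <- function() {
  tibble(
    column_id = names(CORE_PHYSICAL),
    scope = c("variant_genome", "variant_transcript", "variant_transcript"),
    datatype = "text",
    mandatory = TRUE,
    core = TRUE,
    active_for = list("instance-wide", "instance-wide", "instance-wide")
  )
}

physical_name <- function(column_id) {
  if (column_id %in% names(CORE_PHYSICAL)) CORE_PHYSICAL[[column_id]] else column_id
}

#' Define a custom column
#'
#' Registers an optional data field. The column starts inactive; activate it
#' per gene (variant-transcript scope), per disease (phenotype scope) or
#' instance-wide with [activate_column()].
#'
#' @param db An [lovd_instance()].
#' @param column_id Hierarchical name, e.g. `"Phenotype/Age_of_onset"`. The
#'   prefix must match the scope.
#' @param scope One of `"individual"`, `"phenotype"`, `"screening"`,
#'   `"variant_genome"`, `"variant_transcript"`.
#' @param datatype One of `"text"`, `"integer"`, `"decimal"`, `"date"`,
#'   `"select"`.
#' @param mandatory Whether records must carry a non-empty value.
#' @return The registry row, invisibly.
#' @export
define_custom_column <- function(db, column_id, scope, datatype = "text",
                                 mandatory = FALSE) {
  check_mutable(db)
  scope <- arg_match(scope, COLUMN_SCOPES)
  datatype <- arg_match(datatype, COLUMN_DATATYPES)
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*/[A-Za-z][A-Za-z0-9_/]*$", column_id)) {
    abort_validation(sprintf("Malformed column id '%s'.", column_id))
  }
  if (!startsWith(column_id, paste0(SCOPE_PREFIX[[scope]], "/"))) {
    abort_validation(sprintf(
      "Column id '%s' must start with '%s/' for scope %s.",
      column_id, SCOPE_PREFIX[[scope]], scope
    ))
  }
  if (column_id %in% db$columns$column_id) {
    abort_conflict(sprintf("Column %s is already defined.", column_id))
  }
  row <- tibble(column_id = column_id, scope = scope, datatype = datatype,
                mandatory = mandatory, core = FALSE,
                active_for = list(character()))
  db$columns <- bind_rows(db$columns, row)
  invisible(row)
}

column_row <- function(db, column_id) {
  i <- match(column_id, db$columns$column_id)
  if (is.na(i)) abort_validation(sprintf("Unknown column %s.", column_id))
  i
}

#' Activate a custom column for a target
#'
#' Phenotype-scope columns are activated per disease, variant-transcript-scope
#' columns per gene; other scopes (and the special target `"instance-wide"`)
#' apply everywhere. Activation is idempotent. The first activation adds a
#' physical column to the scope's backing table.
#'
#' @param db An [lovd_instance()].
#' @param column_id A defined column id.
#' @param target `"instance-wide"`, a gene symbol, or a disease id, depending
#'   on the column's scope.
#' @return The instance, invisibly.
#' @export
activate_column <- function(db, column_id, target = "instance-wide") {
  check_mutable(db)
  i <- column_row(db, column_id)
  scope <- db$columns$scope[i]
  target <- as.character(target)
  if (target != "instance-wide") {
    if (scope == "phenotype") {
      if (!target %in% as.character(db$diseases$id)) {
        abort_validation("Phenotype-scope columns are activated per disease id.")
      }
    } else if (scope == "variant_transcript") {
      if (!target %in% db$genes$symbol) {
        abort_validation("Variant-transcript-scope columns are activated per gene symbol.")
      }
    } else {
      abort_validation(sprintf(
        "Columns of scope %s can only be activated instance-wide.", scope
      ))
    }
  }
  active <- db$columns$active_for[[i]]
  if (!target %in% active) {
    db$columns$active_for[[i]] <- c(active, target)
  }
  tbl <- SCOPE_TABLE[[scope]]
  phys <- physical_name(column_id)
  if (!phys %in% names(db[[tbl]])) {
    db[[tbl]][[phys]] <- rep(NA_character_, nrow(db[[tbl]]))
  }
  invisible(db)
}

#' Deactivate a custom column for a target
#'
#' Core columns (such as the RNA description) are critical to the data model
#' and are refused. When a non-core column loses its last target its physical
#' column is dropped from the backing table.
#'
#' @inheritParams activate_column
#' @return The instance, invisibly.
#' @export
deactivate_column <- function(db, column_id, target = "instance-wide") {
  check_mutable(db)
  i <- column_row(db, column_id)
  if (db$columns$core[i]) {
    abort_validation(sprintf(
      "Column %s is a core field critical to the data model and can not be removed.",
      column_id
    ))
  }
  db$columns$active_for[[i]] <- setdiff(db$columns$active_for[[i]],
                                        as.character(target))
  if (length(db$columns$active_for[[i]]) == 0) {
    tbl <- SCOPE_TABLE[[db$columns$scope[i]]]
    db[[tbl]][[physical_name(column_id)]] <- NULL
  }
  invisible(db)
}

#' List the custom-column registry
#'
#' @param db An [lovd_instance()].
#' @param scope Optional scope filter.
#' @return Tibble with one row per column; `active_for` is a list column of
#'   targets.
#' @export
list_columns <- function(db, scope = NULL) {
  out <- db$columns
  if (!is.null(scope)) out <- out[out$scope == scope, ]
  out
}

# Is the column active for the given target (gene symbol / disease id)?
column_active_for <- function(db, column_id, target = NULL) {
  i <- match(column_id, db$columns$column_id)
  if (is.na(i)) return(FALSE)
  active <- db$columns$active_for[[i]]
  "instance-wide" %in% active ||
    (!is.null(target) && as.character(target) %in% active)
}

# Validate and fold custom values into a new row, then append to the table.
insert_with_custom <- function(db, table_name, row, custom_values,
                               scope, target = NULL) {
  if (length(custom_values)) {
    if (is.null(names(custom_values)) || any(!nzchar(names(custom_values)))) {
      abort_validation("custom_values must be a named list keyed by column id.")
    }
    for (cid in names(custom_values)) {
      i <- match(cid, db$columns$column_id)
      if (is.na(i) || db$columns$scope[i] != scope) {
        abort_validation(sprintf("Column %s is not defined for scope %s.", cid, scope))
      }
      if (!column_active_for(db, cid, target)) {
        abort_validation(sprintf("Column %s is not active for this record.", cid))
      }
      row[[physical_name(cid)]] <- as.character(custom_values[[cid]])
    }
  }
  bind_rows(db[[table_name]], row)
}
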