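# Role-based access control. Every user is a submitter; extra rights come from
# the two global roles (Database Administrator, Manager — caretakers who can
# view and edit all non-public data), the two per-gene roles (Curator:
# view+edit for the genes in their care; Collaborator: the same visibility
# without edit rights) and per-submitter Colleague grants (view-only or full
# edit over the grantor's records).

#' Create a user account
#'
#' @param db An [lovd_instance()].
#' @param name Display name.
#' @param role_global `"none"` (plain submitter), `"manager"` or `"admin"`.
#' @param curated_genes,collaborator_genes Gene symbols the account curates /
#'   collaborates on.
#' @param auto_import,auto_publish Submission-API behaviour: queued documents
#'   from this account are imported without manager action, and published as
#'   public records, respectively.
#' @param variant_only Whether the account may submit variant-only documents
#'   (no individual attached).
#' @return One-row tibble including the account's API token, invisibly.
#' @export
add_user <- function(db, name, role_global = c("none", "manager", "admin"),
                     curated_genes = character(),
                     collaborator_genes = character(),
                     auto_import = FALSE, auto_publish = FALSE,
                     variant_only = FALSE) {
  check_mutable(db)
  role_global <- arg_match(role_global)
  unknown <- setdiff(c(curated_genes, collaborator_genes), db$genes$symbol)
  if (length(unknown)) {
    abort_validation(sprintf("Unknown gene(s): %s.", paste(unknown, collapse = ", ")))
  }
  id <- next_id(db, "user")
  # Deterministic token derived from the id; unique instance-wide by
  # construction (no RNG involved, so fixture generation stays reproducible).
  token <- sprintf("tok-%08x", (id * 48271L) %% 2147483647L)
  row <- tibble(
    id = id, name = name, role_global = role_global,
    curated_genes = list(curated_genes),
    collaborator_genes = list(collaborator_genes),
    auto_import = auto_import, auto_publish = auto_publish,
    variant_only = variant_only, token = token
  )
  db$users <- bind_rows(db$users, row)
  invisible(row)
}

get_user <- function(db, user_id) {
  if (is.null(user_id) || is.na(user_id)) return(NULL)
  i <- match(user_id, db$users$id)
  if (is.na(i)) NULL else db$users[i, ]
}

user_by_token <- function(db, token) {
  i <- match(token, db$users$token)
  if (is.na(i)) NULL else db$users[i, ]
}

# Resolve a record to (visibility, owner, linked genes). Phenotypes and
# screenings inherit visibility and ownership from their individual.
record_facts <- function(db, kind, id) {
  switch(kind,
    variant = {
      r <- db$variants_genome[db$variants_genome$id == id, ]
      if (nrow(r) == 0) abort_validation("Unknown variant id.")
      list(visibility = r$visibility, owner = r$owner_id,
           genes = variant_genes(db, id))
    },
    individual = {
      r <- db$individuals[db$individuals$id == id, ]
      if (nrow(r) == 0) abort_validation("Unknown individual id.")
      list(visibility = r$visibility, owner = r$owner_id,
           genes = individual_genes(db, id))
    },
    phenotype = {
      r <- db$phenotypes[db$phenotypes$id == id, ]
      if (nrow(r) == 0) abort_validation("Unknown phenotype id.")
      record_facts(db, "individual", r$individual_id)
    },
    screening = {
      r <- db$screenings[db$screenings$id == id, ]
      if (nrow(r) == 0) abort_validation("Unknown screening id.")
      record_facts(db, "individual", r$individual_id)
    },
    abort_validation(sprintf("Unknown record kind '%s'.", kind))
  )
}

has_colleague_grant <- function(db, owner, user_id, need_edit = FALSE) {
  if (is.na(owner)) return(FALSE)
  g <- db$colleague_grants
  hit <- g$grantor_id == owner & g$grantee_id == user_id
  if (!any(hit)) return(FALSE)
  !need_edit || any(g$can_edit[hit])
}

#' Can a user view / edit a record?
#'
#' Pure predicates implementing the role model: public records are viewable by
#' anyone (including anonymous viewers); administrators and managers view and
#' edit everything; curators view and edit, and collaborators view, all
#' records linked to their genes; owners view and edit their own records;
#' colleagues of the owner view, and edit when the grant allows it.
#' `can_edit()` implies `can_view()` for every user and record.
#'
#' @param db An [lovd_instance()].
#' @param user_id User id, or `NULL`/`NA` for an anonymous viewer.
#' @param kind `"variant"`, `"individual"`, `"phenotype"` or `"screening"`.
#' @param record_id Record id.
#' @return Logical flag.
#' @export
can_view <- function(db, user_id, kind, record_id) {
  facts <- record_facts(db, kind, record_id)
  if (identical(facts$visibility, "public")) return(TRUE)
  u <- get_user(db, user_id)
  if (is.null(u)) return(FALSE)
  if (u$role_global %in% c("admin", "manager")) return(TRUE)
  if (!is.na(facts$owner) && facts$owner == u$id) return(TRUE)
  if (any(facts$genes %in% c(u$curated_genes[[1]], u$collaborator_genes[[1]]))) {
    return(TRUE)
  }
  has_colleague_grant(db, facts$owner, u$id, need_edit = FALSE)
}

#' @rdname can_view
#' @export
can_edit <- function(db, user_id, kind, record_id) {
  facts <- record_facts(db, kind, record_id)
  u <- get_user(db, user_id)
  if (is.null(u)) return(FALSE)
  if (u$role_global %in% c("admin", "manager")) return(TRUE)
  if (!is.na(facts$owner) && facts$owner == u$id) return(TRUE)
  if (any(facts$genes %in% u$curated_genes[[1]])) return(TRUE)
  has_colleague_grant(db, facts$owner, u$id, need_edit = TRUE)
}

#' Grant or revoke Colleague rights
#'
#' Any submitter can assign Colleagues with view-only or full edit rights over
#' their own submissions.
#'
#' @param db An [lovd_instance()].
#' @param grantor_id,grantee_id Existing, distinct user ids.
#' @param can_edit Whether the grant carries edit rights.
#' @return The instance, invisibly.
#' @export
grant_colleague <- function(db, grantor_id, grantee_id, can_edit = FALSE) {
  check_mutable(db)
  if (is.null(get_user(db, grantor_id)) || is.null(get_user(db, grantee_id))) {
    abort_validation("Both accounts must exist.")
  }
  if (grantor_id == grantee_id) {
    abort_validation("A user can not grant Colleague rights to themselves.")
  }
  g <- db$colleague_grants
  g <- g[!(g$grantor_id == grantor_id & g$grantee_id == grantee_id), ]
  db$colleague_grants <- bind_rows(
    g, tibble(grantor_id = as.integer(grantor_id),
              grantee_id = as.integer(grantee_id), can_edit = can_edit)
  )
  invisible(db)
}

#' @rdname grant_colleague
#' @export
revoke_colleague <- function(db, grantor_id, grantee_id) {
  check_mutable(db)
  g <- db$colleague_grants
  db$colleague_grants <- g[!(g$grantor_id == grantor_id &
                               g$grantee_id == grantee_id), ]
  invisible(db)
}

#' Record a curator's classification on a transcript annotation
#'
#' Sets the concluded effect while always retaining the submitter's original
#' reported classification. Only users with curator-level edit rights on the
#' record's gene (or a global role) may classify; collaborators and plain
#' submitters are refused.
#'
#' @param db An [lovd_instance()].
#' @param user_id Acting user.
#' @param genomic_variant_id,transcript_accession Identify the annotation row.
#' @param effect New concluded effect class.
#' @return The updated annotation row, invisibly.
#' @export
record_curator_classification <- function(db, user_id, genomic_variant_id,
                                          transcript_accession, effect) {
  check_mutable(db)
  effect <- check_effect_class(effect)
  u <- get_user(db, user_id)
  if (is.null(u)) abort_authorization("Unknown user.")
  genes <- variant_genes(db, genomic_variant_id)
  curator_here <- u$role_global %in% c("admin", "manager") ||
    any(genes %in% u$curated_genes[[1]])
  if (!curator_here) {
    abort_authorization(
      "Only curators of the record's gene (or managers) may record a classification."
    )
  }
  idx <- which(db$variants_transcript$genomic_variant_id == genomic_variant_id &
                 db$variants_transcript$transcript_accession == transcript_accession)
  if (length(idx) == 0) abort_validation("No such transcript annotation.")
  db$variants_transcript$effect_concluded[idx] <- effect
  gi <- which(db$variants_genome$id == genomic_variant_id)
  db$variants_genome$edited_at[gi] <- utc_now()
  invisible(db$variants_transcript[idx, ])
}
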