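KB_SCHEMA_VERSION <- "1.0"

mf_to_list <- function(mf) {
  if (inherits(mf, "piecewise_mf")) {
    seg <- mf$segments
    n <- nrow(seg)
    list(kind = "piecewise_linear",
         segments = lapply(seq_len(n), function(i) {
           list(lower = seg$lower[i], upper = seg$upper[i],
                slope = seg$slope[i], intercept = seg$intercept[i],
                upper_closed = (i == n))
         }))
  } else {
    list(kind = "bell", b = mf$b, c = mf$c)
  }
}

reject_unknown <- function(obj, allowed, where) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra)) {
    fc_stop(sprintf("unknown field(s) at %s: %s", where,
                    paste(extra, collapse = ", ")),
            "fuzzycad_validation_error")
  }
}

require_fields <- function(obj, fields, where) {
  missing <- setdiff(fields, names(obj))
  if (length(missing)) {
    fc_stop(sprintf("missing field(s) at %s: %s", where,
                    paste(missing, collapse = ", ")),
            "fuzzycad_validation_error")
  }
}

mf_from_list <- function(doc, domain, where) {
  require_fields(doc, "kind", where)
  if (identical(doc$kind, "piecewise_linear")) {
    reject_unknown(doc, c("kind", "segments"), where)
    require_fields(doc, "segments", where)
    seg <- do.call(rbind, lapply(seq_along(doc$segments), function(i) {
      s <- doc$segments[[i]]
      w <- sprintf("%s.segments[%d]", where, i)
      require_fields(s, c("lower", "upper", "slope", "intercept"), w)
      reject_unknown(s, c("lower", "upper", "slope", "intercept",
                          "upper_closed"), w)
      data.frame(lower = s$lower, upper = s$upper, slope = s$slope,
                 intercept = s$intercept)
    }))
    piecewise_mf(seg, domain)
  } else if (identical(doc$kind, "bell")) {
    reject_unknown(doc, c("kind", "b", "c"), where)
    require_fields(doc, c("b", "c"), where)
    bell_mf(doc$b, doc$c, domain)
  } else {
    fc_stop(sprintf("unknown membership kind '%s' at %s", doc$kind, where),
            "fuzzycad_validation_error")
  }
}

#' Save / load a knowledge base
#'
#' `save_knowledge_base()` writes the JSON representation (schema: top-level
#' fields `schema_version`, `metadata`, `factors`, `rules`; each factor has
#' `id`, `description`, `domain`, `terms`; each rule has `antecedent`,
#' `consequent`, `weight`). `load_knowledge_base()` reads it back — YAML files
#' (`.yaml` / `.yml`) are also accepted on load — validating strictly: unknown
#' fields, unknown factor or term identifiers, malformed segments and weights
#' outside `[0, 1]` are rejected with a message naming the offending path.
#' Round-tripping a knowledge base reproduces it field for field.
#'
#' @param kb a [knowledge_base()].
#' @param path file path.
#' @return `load_knowledge_base()` returns a [knowledge_base()];
#'   `save_knowledge_base()` returns `path` invisibly.
#' @export
save_knowledge_base <- function(kb, path) {
  stopifnot(inherits(kb, "knowledge_base"))
  ids <- names(kb$variables)
  doc <- list(
    schema_version = KB_SCHEMA_VERSION,
    metadata = kb$metadata,
    factors = lapply(ids, function(id) {
      v <- kb$variables[[id]]
      list(id = id, description = v$description,
           domain = v$domain,
           terms = lapply(setNames(TERM_LABELS, TERM_LABELS),
                          function(lab) mf_to_list(v$terms[[lab]])))
    }),
    rules = lapply(seq_len(nrow(kb$rules)), function(r) {
      list(antecedent = as.list(setNames(
             vapply(ids, function(id) kb$rules[[id]][r], character(1)), ids)),
           consequent = kb$rules$class[r],
           weight = kb$rules$weight[r])
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_knowledge_base
#' @export
load_knowledge_base <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  reject_unknown(doc, c("schema_version", "metadata", "factors", "rules"),
                 "top level")
  require_fields(doc, c("schema_version", "factors", "rules"), "top level")
  variables <- list()
  for (f in doc$factors) {
    where <- sprintf("factors[%s]", if (is.null(f$id)) "?" else f$id)
    require_fields(f, c("id", "description", "domain", "terms"), where)
    reject_unknown(f, c("id", "description", "domain", "terms"), where)
    domain <- as.numeric(unlist(f$domain))
    reject_unknown(f$terms, TERM_LABELS, paste0(where, ".terms"))
    require_fields(f$terms, TERM_LABELS, paste0(where, ".terms"))
    terms <- lapply(setNames(TERM_LABELS, TERM_LABELS), function(lab) {
      mf_from_list(f$terms[[lab]], domain,
                   sprintf("%s.terms.%s", where, lab))
    })
    variables[[f$id]] <- linguistic_variable(f$id, f$description, domain, terms)
  }
  ids <- names(variables)
  rules <- do.call(rbind, lapply(seq_along(doc$rules), function(r) {
    rl <- doc$rules[[r]]
    where <- sprintf("rules[%d]", r)
    require_fields(rl, c("antecedent", "consequent", "weight"), where)
    reject_unknown(rl, c("antecedent", "consequent", "weight"), where)
    bad <- setdiff(names(rl$antecedent), ids)
    if (length(bad)) {
      fc_stop(sprintf("%s references undefined factor(s): %s", where,
                      paste(bad, collapse = ", ")),
              "fuzzycad_validation_error")
    }
    require_fields(rl$antecedent, ids, paste0(where, ".antecedent"))
    row <- as.data.frame(lapply(rl$antecedent[ids], as.character))
    row$class <- as.character(rl$consequent)
    row$weight <- as.numeric(rl$weight)
    row
  }))
  kb <- knowledge_base(variables, rules,
                       metadata = if (is.null(doc$metadata)) "" else doc$metadata)
  val <- validate_knowledge_base(kb, grid_step = 0.05)
  if (!val$ok) {
    fc_warn(sprintf("loaded knowledge base has issues: %s",
                    paste(c(
                      if (length(val$duplicate_rules))
                        sprintf("duplicate rules (%s)",
                                paste(val$duplicate_rules, collapse = ",")),
                      if (length(val$uncovered_classes))
                        sprintf("uncovered class(es) %s",
                                paste(val$uncovered_classes, collapse = ","))),
                      collapse = "; ")),
            "fuzzycad_kb_coverage_warning")
  }
  kb
}
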