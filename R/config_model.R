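# Configuration model: archive endpoints, governance policies, projects.
#
# The configuration is a single YAML document. Key names are part of the
# public contract (see the package vignette for the full schema):
#   endpoints[].{id,institution,department,aet,host,port,mrn_rule}
#   policies.<endpoint_id>.{max_concurrent,max_studies_per_patient,
#                           windows[].{days,start,end,rate_count,rate_period}}
#   projects[].{id,irb_id,members,allowlist,expiration,cache_quota_bytes}
#   cache_root, audit_store

DAY_NAMES <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

#' Default medical-record-number normalization rule
#'
#' Used for project allowlists at load time (allowlists are endpoint
#' independent) and for any endpoint that does not declare its own rule:
#' hyphens and spaces are stripped and letters are upper-cased; no padding
#' or prefix is applied.
#'
#' @return an `mrn_rule` object
#' @export
default_mrn_rule <- function() {
  mrn_rule(strip_chars = "- ", uppercase = TRUE)
}

#' Construct an MRN format rule
#'
#' Clinical sites issue medical record numbers in different shapes
#' (dashed, zero-padded, letter-prefixed). A rule maps any accepted raw
#' form onto one canonical form so allowlist membership and audit joins
#' are format-independent.
#'
#' @param strip_chars characters removed from the raw value (a string,
#'   each character removed individually)
#' @param uppercase fold letters to upper case
#' @param pad_width left zero-pad the core identifier to this width
#' @param prefix literal prepended after padding
#' @export
mrn_rule <- function(strip_chars = "", uppercase = FALSE,
                     pad_width = NULL, prefix = NULL) {
  r <- list(strip_chars = strip_chars %||% "",
            uppercase = isTRUE(uppercase),
            pad_width = pad_width, prefix = prefix)
  if (!is.null(r$pad_width)) {
    r$pad_width <- as.integer(r$pad_width)
    if (r$pad_width < 1L)
      pb_validation_error("mrn_rule.pad_width", "pad_width must be >= 1")
  }
  structure(r, class = "mrn_rule")
}

#' Normalize a raw MRN to canonical form
#'
#' Deterministic and idempotent: applying the rule to an already-canonical
#' MRN returns it unchanged. A value that already carries the rule's
#' prefix (after stripping and case-folding) is treated as canonical and
#' is not re-padded.
#'
#' @param raw raw identifier text
#' @param rule an [mrn_rule()]
#' @return canonical MRN string
#' @export
normalize_mrn <- function(raw, rule = default_mrn_rule()) {
  stopifnot(is.character(raw))
  vapply(raw, function(x) {
    if (nzchar(rule$strip_chars)) {
      for (ch in strsplit(rule$strip_chars, "")[[1]])
        x <- gsub(ch, "", x, fixed = TRUE)
    }
    if (rule$uppercase) x <- toupper(x)
    if (!nzchar(x))
      pb_stop("pb_invalid_mrn", sprintf("MRN '%s' is empty after stripping", raw))
    pre <- rule$prefix %||% ""
    if (nzchar(pre) && startsWith(x, pre)) return(x)
    if (!is.null(rule$pad_width) && nchar(x) < rule$pad_width)
      x <- paste0(strrep("0", rule$pad_width - nchar(x)), x)
    paste0(pre, x)
  }, character(1), USE.NAMES = FALSE)
}

#' Load and validate a system configuration
#'
#' Parses the YAML configuration and checks every structural invariant:
#' unique endpoint ids, AE titles of 1-16 printable characters, ports in
#' 1-65535, exactly one governance policy per endpoint, non-overlapping
#' access windows, non-empty project membership and allowlists, and
#' positive cache quotas. Project allowlists are normalized with
#' [default_mrn_rule()] at load time.
#'
#' @param source path to a YAML file, or a single string containing YAML
#' @return a validated `system_config` object
#' @export
load_config <- function(source) {
  txt <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    paste(readLines(source, warn = FALSE), collapse = "\n") else source
  doc <- tryCatch(yaml::yaml.load(txt),
                  error = function(e) pb_syntax_error(
                    paste0("configuration syntax error: ", conditionMessage(e))))
  if (!is.list(doc)) pb_syntax_error("configuration is not a mapping")
  validate_config(doc)
}

validate_config <- function(doc) {
  need <- function(x, field) {
    if (is.null(x)) pb_validation_error(field, "required field is missing")
    x
  }
  cfg <- list()
  cfg$cache_root <- need(doc$cache_root, "cache_root")
  cfg$audit_store <- need(doc$audit_store, "audit_store")
  cfg$timezone <- doc$timezone %||% Sys.timezone()

  eps <- need(doc$endpoints, "endpoints")
  cfg$endpoints <- lapply(eps, function(e) {
    id <- need(e$id, "endpoints[].id")
    aet <- need(e$aet, "endpoints[].aet")
    if (nchar(aet) < 1 || nchar(aet) > 16 || grepl("[^\x20-\x7e]", aet))
      pb_validation_error(sprintf("endpoints[%s].aet", id),
                          "application-entity title must be 1-16 printable characters")
    port <- as.integer(need(e$port, sprintf("endpoints[%s].port", id)))
    if (is.na(port) || port < 1 || port > 65535)
      pb_validation_error(sprintf("endpoints[%s].port", id), "port must be in 1-65535")
    rule <- if (is.null(e$mrn_rule)) default_mrn_rule()
            else do.call(mrn_rule, e$mrn_rule)
    structure(list(id = id, institution = need(e$institution,
                     sprintf("endpoints[%s].institution", id)),
                   department = e$department, aet = aet,
                   host = need(e$host, sprintf("endpoints[%s].host", id)),
                   port = port, mrn_rule = rule),
              class = "pacs_endpoint")
  })
  ep_ids <- vapply(cfg$endpoints, `[[`, "", "id")
  if (anyDuplicated(ep_ids))
    pb_validation_error("endpoints[].id",
                        sprintf("endpoint id '%s' is not unique",
                                ep_ids[duplicated(ep_ids)][1]))

  pols <- need(doc$policies, "policies")
  for (pid in names(pols))
    if (!pid %in% ep_ids)
      pb_validation_error(sprintf("policies.%s", pid),
                          sprintf("policy references unknown endpoint '%s'", pid))
  for (eid in ep_ids)
    if (!eid %in% names(pols))
      pb_validation_error(sprintf("policies.%s", eid),
                          sprintf("endpoint '%s' has no governance policy", eid))
  cfg$policies <- lapply(pols, validate_policy)
  names(cfg$policies) <- names(pols)

  prjs <- need(doc$projects, "projects")
  cfg$projects <- lapply(prjs, validate_project)
  prj_ids <- vapply(cfg$projects, `[[`, "", "id")
  if (anyDuplicated(prj_ids))
    pb_validation_error("projects[].id",
                        sprintf("project id '%s' is not unique",
                                prj_ids[duplicated(prj_ids)][1]))
  names(cfg$projects) <- prj_ids
  names(cfg$endpoints) <- ep_ids
  structure(cfg, class = "system_config")
}

validate_policy <- function(p) {
  mc <- as.integer(p$max_concurrent %||% NA)
  if (is.na(mc) || mc < 0)
    pb_validation_error("policies.max_concurrent", "must be an integer >= 0")
  msp <- p$max_studies_per_patient
  if (!is.null(msp)) {
    msp <- as.integer(msp)
    if (is.na(msp) || msp < 1)
      pb_validation_error("policies.max_studies_per_patient", "must be an integer >= 1")
  }
  ws <- lapply(p$windows %||% list(), validate_window)
  # overlap check on (day, minute) expansion
  for (d in DAY_NAMES) {
    ivs <- do.call(rbind, lapply(ws, function(w)
      if (d %in% w$days) c(w$start, w$end) else NULL))
    if (!is.null(ivs) && nrow(ivs) > 1) {
      o <- order(ivs[, 1])
      ivs <- ivs[o, , drop = FALSE]
      if (any(ivs[-nrow(ivs), 2] > ivs[-1, 1]))
        pb_validation_error("policies.windows",
                            sprintf("windows overlap on %s", d))
    }
  }
  structure(list(windows = ws, max_concurrent = mc,
                 max_studies_per_patient = msp),
            class = "governance_policy")
}

validate_window <- function(w) {
  days <- w$days
  if (is.null(days) || !all(days %in% DAY_NAMES))
    pb_validation_error("windows[].days",
                        sprintf("days must be a subset of %s",
                                paste(DAY_NAMES, collapse = ",")))
  start <- as.integer(w$start); end <- as.integer(w$end)
  if (is.na(start) || start < 0 || start >= 1440)
    pb_validation_error("windows[].start", "start must be a minute-of-day in [0,1440)")
  if (is.na(end) || end <= 0 || end > 1440)
    pb_validation_error("windows[].end", "end must be a minute-of-day in (0,1440]")
  if (!(start < end))
    pb_validation_error("windows[].start", "start < end is required")
  rc <- as.integer(w$rate_count)
  if (is.na(rc) || rc < 0)
    pb_validation_error("windows[].rate_count", "must be an integer >= 0")
  rp <- w$rate_period
  if (is.null(rp) || !rp %in% c("minute", "hour"))
    pb_validation_error("windows[].rate_period", "must be 'minute' or 'hour'")
  structure(list(days = days, start = start, end = end,
                 rate_count = rc, rate_period = rp),
            class = "access_window")
}

validate_project <- function(p) {
  id <- p$id
  if (is.null(id)) pb_validation_error("projects[].id", "required field is missing")
  members <- as.character(p$members %||% character(0))
  if (length(members) == 0)
    pb_validation_error(sprintf("projects[%s].members", id), "members must be non-empty")
  allow <- as.character(p$allowlist %||% character(0))
  if (length(allow) == 0)
    pb_validation_error(sprintf("projects[%s].allowlist", id), "allowlist must be non-empty")
  allow <- unique(normalize_mrn(allow, default_mrn_rule()))
  quota <- as.numeric(p$cache_quota_bytes %||% NA)
  if (is.na(quota) || quota <= 0)
    pb_validation_error(sprintf("projects[%s].cache_quota_bytes", id),
                        "cache_quota_bytes must be > 0")
  exp <- if (!is.null(p$expiration)) as.Date(p$expiration) else NULL
  structure(list(id = id, irb_id = p$irb_id %||% "",
                 members = members, allowlist = allow,
                 expiration = exp, cache_quota_bytes = quota),
            class = "project")
}

#' Serialize a configuration back to YAML
#'
#' `load_config(serialize_config(cfg))` is a fixed point: the reloaded
#' object is identical to `cfg`.
#'
#' @param cfg a `system_config`
#' @return a YAML string
#' @export
serialize_config <- function(cfg) {
  stopifnot(inherits(cfg, "system_config"))
  strip <- function(x) { attributes(x) <- list(names = names(x)); x }
  doc <- list(
    cache_root = cfg$cache_root,
    audit_store = cfg$audit_store,
    timezone = cfg$timezone,
    endpoints = lapply(unname(cfg$endpoints), function(e) {
      e <- strip(e)
      e$mrn_rule <- Filter(Negate(is.null), strip(e$mrn_rule))
      Filter(Negate(is.null), e)
    }),
    policies = lapply(cfg$policies, function(p) {
      out <- list(max_concurrent = p$max_concurrent)
      if (!is.null(p$max_studies_per_patient))
        out$max_studies_per_patient <- p$max_studies_per_patient
      out$windows <- lapply(p$windows, strip)
      out
    }),
    projects = lapply(unname(cfg$projects), function(p) {
      p <- strip(p)
      if (!is.null(p$expiration)) p$expiration <- format(p$expiration)
      Filter(Negate(is.null), p)
    })
  )
  yaml::as.yaml(doc)
}

#' @export
print.system_config <- function(x, ...) {
  cat(sprintf("<system_config> %d endpoint(s), %d project(s)\n",
              length(x$endpoints), length(x$projects)))
  cat("  cache_root:", x$cache_root, "\n")
  invisible(x)
}
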