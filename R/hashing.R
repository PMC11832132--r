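#' Canonicalize the identifying triple
#'
#' Normalizes the three identifying fields that feed the anonymous
#' identifier so that cosmetic differences between provider extracts
#' (case, whitespace, date dialect, gender spelling) cannot break
#' linkage. The canonical forms are: service number uppercased with all
#' whitespace removed; date of birth rendered ISO-8601 (`YYYY-MM-DD`);
#' gender mapped onto the fixed token set `M`, `F`, `O`.
#'
#' Canonicalization is idempotent: applying it to already-canonical
#' values returns them unchanged.
#'
#' @param service_number character vector of provider-recorded service
#'   numbers.
#' @param date_of_birth `Date` vector, or character vector parsed
#'   according to `date_format`.
#' @param gender character vector; accepted spellings (case-insensitive)
#'   are `m`/`male`, `f`/`female`, `o`/`other`/`non-binary`/`nonbinary`.
#' @param date_format date dialect for character input: `"ymd"`
#'   (ISO-8601, default), `"dmy"` (day-first, e.g. `01/03/1960` is
#'   1 March 1960) or `"mdy"` (month-first). ISO-8601 input is accepted
#'   under every dialect. There is no guessing: a row that does not
#'   parse under the configured dialect is an error.
#' @return a tibble with columns `service_number`, `date_of_birth`
#'   (`Date`) and `gender`, one row per input record.
#' @export
#' @examples
#' canonicalize_key(" ab123 4 ", "01/03/1960", "male", date_format = "dmy")
canonicalize_key <- function(service_number, date_of_birth, gender,
                             date_format = c("ymd", "dmy", "mdy")) {
  date_format <- match.arg(date_format)
  n <- length(service_number)
  if (length(date_of_birth) != n || length(gender) != n) {
    stop_vetlink("identity fields must have equal lengths",
                 "vetlink_validation_error")
  }

  sn <- toupper(gsub("[[:space:]]+", "", as.character(service_number)))
  bad_sn <- which(is.na(service_number) | sn == "")
  if (length(bad_sn)) {
    stop_vetlink(
      sprintf("empty service number in record(s): %s",
              paste(head(bad_sn, 5), collapse = ", ")),
      "vetlink_validation_error"
    )
  }

  dob <- parse_identity_date(date_of_birth, date_format)
  bad_dob <- which(is.na(dob))
  if (length(bad_dob)) {
    stop_vetlink(
      sprintf("unparseable date of birth in record(s): %s",
              paste(head(bad_dob, 5), collapse = ", ")),
      "vetlink_validation_error"
    )
  }

  g <- canonical_gender(gender)
  bad_g <- which(is.na(g))
  if (length(bad_g)) {
    stop_vetlink(
      sprintf("unmappable gender %s in record(s): %s",
              paste(unique(gender[bad_g]), collapse = "/"),
              paste(head(bad_g, 5), collapse = ", ")),
      "vetlink_validation_error"
    )
  }

  tibble::tibble(service_number = sn, date_of_birth = dob, gender = g)
}

parse_identity_date <- function(x, date_format) {
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  iso <- as.Date(x, format = "%Y-%m-%d")
  alt <- switch(date_format,
    ymd = iso,
    dmy = combine_first(as.Date(x, format = "%d/%m/%Y"),
                        as.Date(x, format = "%d-%m-%Y")),
    mdy = combine_first(as.Date(x, format = "%m/%d/%Y"),
                        as.Date(x, format = "%m-%d-%Y"))
  )
  combine_first(iso, alt)
}

combine_first <- function(a, b) {
  a[is.na(a)] <- b[is.na(a)]
  a
}

canonical_gender <- function(gender) {
  g <- tolower(trimws(as.character(gender)))
  map <- c(
    m = "M", male = "M",
    f = "F", female = "F",
    o = "O", other = "O", `non-binary` = "O", nonbinary = "O"
  )
  unname(map[g])
}

#' Compute the salted anonymous identifier
#'
#' Hashes the canonical identifying triple together with a provider salt
#' into a 64-character lowercase hexadecimal SHA-256 digest, the sole
#' person key used downstream. SHA-256 is the member of the SHA family
#' whose digest prints as exactly 64 hexadecimal digits. The message is
#' the canonical fields joined in fixed order by `|`:
#' `service_number|YYYY-MM-DD|gender|salt`. The salt keeps the key space
#' outside dictionary reach; hashing without one is refused. Records of
#' the same person hashed by different providers link if, and only if,
#' the providers share the salt.
#'
#' The pre-image (the identifying triple and salt) is never stored,
#' logged or attached to the result.
#'
#' @param key a tibble from [canonicalize_key()] (columns
#'   `service_number`, `date_of_birth`, `gender`).
#' @param salt a single non-empty secret string.
#' @return character vector of 64-hex-digit identifiers, one per row of
#'   `key`.
#' @export
hash_identity <- function(key, salt) {
  req <- c("service_number", "date_of_birth", "gender")
  if (!all(req %in% names(key))) {
    stop_vetlink("`key` must carry service_number, date_of_birth and gender",
                 "vetlink_validation_error")
  }
  if (missing(salt) || is.null(salt) || length(salt) != 1 ||
      is.na(salt) || !nzchar(salt)) {
    stop_vetlink("refusing to hash without a non-empty salt",
                 "vetlink_security_error")
  }
  msg <- paste(key$service_number,
               format(key$date_of_birth, "%Y-%m-%d"),
               key$gender, salt, sep = "|")
  as.character(openssl::sha256(msg))
}

#' Remove identifying fields from hashed records
#'
#' Drops every field in the identifying set (service number, date of
#' birth, salt) from a record table that already carries `hashed_id`,
#' leaving the hash as the sole person key. If both `date_of_birth` and
#' an event `date` are present, the date of birth is first converted to
#' `age_at_event` (completed whole years at the event date) so that age
#' can still be derived downstream. Gender is retained: it is an
#' analysis exposure, not a linkage risk once the hash replaces the
#' triple.
#'
#' @param records a data frame with a `hashed_id` column.
#' @return the records with columns `service_number`, `date_of_birth`
#'   and `salt` removed (and `age_at_event` added when derivable).
#' @export
strip_identifiers <- function(records) {
  if (!"hashed_id" %in% names(records)) {
    stop_vetlink(
      "records carry no `hashed_id`; hash before stripping identifiers",
      "vetlink_pipeline_order_error"
    )
  }
  if (all(c("date_of_birth", "date") %in% names(records)) &&
      !"age_at_event" %in% names(records)) {
    records$age_at_event <- compute_age(records$date_of_birth, records$date)
  }
  drop <- intersect(c("service_number", "date_of_birth", "salt"),
                    names(records))
  records[setdiff(names(records), drop)]
}

#' Anonymize one provider extract
#'
#' Convenience wrapper chaining [canonicalize_key()], [hash_identity()]
#' and [strip_identifiers()] over a raw extract: the result carries
#' `hashed_id` and per-event age in place of the identifying triple.
#'
#' @param extract raw extract tibble with `service_number`,
#'   `date_of_birth`, `gender` and an event `date` column.
#' @param salt provider salt (see [hash_identity()]).
#' @param date_format date dialect of the extract, see
#'   [canonicalize_key()].
#' @return the anonymized extract.
#' @export
anonymize_extract <- function(extract, salt, date_format = "ymd") {
  key <- canonicalize_key(extract$service_number, extract$date_of_birth,
                          extract$gender, date_format = date_format)
  extract$gender <- key$gender
  extract$date_of_birth <- key$date_of_birth
  if (!inherits(extract$date, "Date")) {
    extract$date <- parse_identity_date(extract$date, date_format)
  }
  extract$hashed_id <- hash_identity(key, salt)
  strip_identifiers(extract)
}
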