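## Corpus handling: tokenization, vocabulary, fixed-shape report/tag
## encodings, and the JSONL manifest / CSV tag-catalog file formats.

RESERVED_TOKENS <- c("<pad>", "<unk>", "<bos>", "<eos>")
PAD_ID <- 1L
UNK_ID <- 2L
BOS_ID <- 3L
EOS_ID <- 4L

#' Tokenize a sentence
#'
#' Lowercases, strips the punctuation characters `.,;:!?()"` and splits on
#' whitespace. This is the single tokenizer shared by vocabulary
#' construction, report encoding and all text metrics.
#'
#' @param sentence a character string
#' @return character vector of tokens (length 0 for an empty string)
#' @examples
#' tokenize("The heart is Normal.")
#' @export
tokenize <- function(sentence) {
  s <- tolower(sentence)
  s <- gsub('[.,;:!?()"]', " ", s)
  out <- strsplit(trimws(s), "\\s+")[[1]]
  out[nzchar(out)]
}

#' Build a word vocabulary from a corpus of reports
#'
#' Words occurring fewer than `min_count` times map to the unknown token.
#' The vocabulary opens with the four reserved tokens `<pad>`, `<unk>`,
#' `<bos>`, `<eos>` (ids 1..4) followed by retained words ordered by
#' descending corpus frequency, ties broken lexicographically, so two
#' builds from the same corpus are identical.
#'
#' @param reports list of reports, each a character vector of sentences
#' @param min_count minimum corpus frequency for a word to be retained
#' @return object of class `rg_vocabulary`: list with `tokens`, `index`
#'   (named integer lookup) and `min_count`
#' @export
build_vocabulary <- function(reports, min_count = 3L) {
  stopifnot(min_count >= 1)
  words <- unlist(lapply(reports, function(r) unlist(lapply(r, tokenize))))
  tokens <- RESERVED_TOKENS
  if (length(words)) {
    tab <- table(words)
    keep <- tab[tab >= min_count]
    if (length(keep)) {
      ord <- order(-as.integer(keep), names(keep))
      tokens <- c(tokens, names(keep)[ord])
    }
  }
  vocab <- list(tokens = tokens,
                index = stats::setNames(seq_along(tokens), tokens),
                min_count = as.integer(min_count))
  class(vocab) <- "rg_vocabulary"
  vocab
}

token_ids <- function(words, vocab) {
  ids <- unname(vocab$index[words])
  ids[is.na(ids)] <- UNK_ID
  as.integer(ids)
}

#' Read or write a vocabulary file (one token per line; line number = id)
#' @param vocab an `rg_vocabulary`
#' @param path file path
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path)
  if (!identical(tokens[seq_len(4)], RESERVED_TOKENS)) {
    stopf("vocabulary file %s does not start with the reserved tokens", path)
  }
  vocab <- list(tokens = tokens,
                index = stats::setNames(seq_along(tokens), tokens),
                min_count = NA_integer_)
  class(vocab) <- "rg_vocabulary"
  vocab
}

#' Encode a report into fixed-shape training targets
#'
#' Keeps at most `s_max` sentences; each is tokenized, truncated to
#' `w_max - 2` content tokens, wrapped in `<bos>`/`<eos>` and padded to
#' `w_max`. The stop vector marks, per sentence slot, whether generation
#' should halt after that sentence: 0 for all real sentences but the last,
#' 1 from the last real sentence onward (padded slots included).
#'
#' @param report character vector of sentences (length >= 1)
#' @param vocab an `rg_vocabulary`
#' @param s_max maximum number of sentences retained
#' @param w_max total token slots per sentence incl. `<bos>`/`<eos>`
#' @return list with `token_ids` (`s_max` x `w_max` integer matrix),
#'   `lengths` (true lengths incl. specials, 0 for padded slots), `stop`
#'   (length-`s_max` 0/1 vector) and `n_sentences`
#' @export
encode_report <- function(report, vocab, s_max = 6L, w_max = 30L) {
  stopifnot(s_max >= 1, w_max >= 3)
  if (length(report) == 0L) {
    stopf("invalid study: report has no sentences")
  }
  kept <- report[seq_len(min(length(report), s_max))]
  s <- length(kept)
  ids <- matrix(PAD_ID, s_max, w_max)
  lens <- integer(s_max)
  for (i in seq_len(s)) {
    w <- tokenize(kept[i])
    w <- w[seq_len(min(length(w), w_max - 2L))]
    row <- c(BOS_ID, token_ids(w, vocab), EOS_ID)
    ids[i, seq_along(row)] <- row
    lens[i] <- length(row)
  }
  stop_vec <- as.integer(seq_len(s_max) >= s)
  list(token_ids = ids, lengths = lens, stop = stop_vec, n_sentences = s)
}

#' Decode a row of token ids back to words (reserved tokens stripped)
#' @param ids integer vector of token ids
#' @param vocab an `rg_vocabulary`
#' @export
decode_tokens <- function(ids, vocab) {
  ids <- ids[ids > length(RESERVED_TOKENS)]
  vocab$tokens[ids]
}

## ---- tag catalog ---------------------------------------------------------

#' Create a tag catalog
#'
#' The catalog fixes the ordered index space of the `M` lesion tags used as
#' multi-label classification targets.
#' @param names character vector of unique tag names
#' @return object of class `rg_tag_catalog`
#' @export
tag_catalog <- function(names) {
  names <- as.character(names)
  if (anyDuplicated(names)) stopf("tag names must be unique")
  if (length(names) < 1L) stopf("catalog needs at least one tag")
  cat <- list(names = names,
              index = stats::setNames(seq_along(names), names))
  class(cat) <- "rg_tag_catalog"
  cat
}

#' Read/write a tag catalog as CSV (`index,name`, 0-based contiguous index)
#' @param catalog an `rg_tag_catalog`
#' @param path CSV file path
#' @export
write_tag_catalog <- function(catalog, path) {
  utils::write.csv(
    data.frame(index = seq_along(catalog$names) - 1L, name = catalog$names),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tag_catalog
#' @export
read_tag_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "name") %in% names(df))) {
    stopf("tag catalog %s must have columns index,name", path)
  }
  df <- df[order(df$index), ]
  if (!identical(as.integer(df$index), seq_len(nrow(df)) - 1L)) {
    stopf("tag catalog %s indices must be 0-based and contiguous", path)
  }
  tag_catalog(df$name)
}

#' Encode tag names as a multi-hot vector over the catalog
#' @param tag_names character vector (possibly empty, duplicates allowed)
#' @param catalog an `rg_tag_catalog`
#' @return integer 0/1 vector of length `M`
#' @export
encode_tags <- function(tag_names, catalog) {
  v <- integer(length(catalog$names))
  if (length(tag_names)) {
    idx <- catalog$index[tag_names]
    if (anyNA(idx)) {
      stopf("unknown tag name(s): %s",
            paste(tag_names[is.na(idx)], collapse = ", "))
    }
    v[unique(unname(idx))] <- 1L
  }
  v
}

## ---- studies and manifest ------------------------------------------------

#' Construct a study record
#' @param study_id string identifier
#' @param frontal_path,lateral_path paths to 8-bit grayscale PNGs
#' @param tags character vector of tag names present in the study
#' @param report character vector of diagnostic sentences
#' @export
study <- function(study_id, frontal_path, lateral_path, tags, report) {
  s <- list(study_id = as.character(study_id),
            frontal_path = as.character(frontal_path),
            lateral_path = as.character(lateral_path),
            tags = as.character(tags),
            report = as.character(report))
  class(s) <- "rg_study"
  s
}

MANIFEST_FIELDS <- c("study_id", "frontal_path", "lateral_path", "tags", "report")

#' Read or write a study manifest (JSONL, one study per line)
#'
#' Image paths are interpreted relative to the manifest's directory when not
#' absolute. `read_manifest()` verifies that both image files exist.
#'
#' @param studies list of `rg_study`
#' @param path manifest file path
#' @return `read_manifest()` returns a list of `rg_study`
#' @export
write_manifest <- function(studies, path) {
  lines <- vapply(studies, function(s) {
    jsonlite::toJSON(list(study_id = jsonlite::unbox(s$study_id),
                          frontal_path = jsonlite::unbox(s$frontal_path),
                          lateral_path = jsonlite::unbox(s$lateral_path),
                          tags = s$tags, report = s$report))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @param check_images verify the referenced image files exist
#' @export
read_manifest <- function(path, check_images = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  base <- dirname(normalizePath(path, mustWork = TRUE))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj)) stopf("manifest %s: malformed JSON on line %d", path, i)
    missing <- setdiff(MANIFEST_FIELDS, names(obj))
    if (length(missing)) {
      stopf("manifest %s line %d: missing field(s) %s",
            path, i, paste(missing, collapse = ", "))
    }
    fp <- resolve_path(obj$frontal_path, base)
    lp <- resolve_path(obj$lateral_path, base)
    if (check_images) {
      for (p in c(fp, lp)) {
        if (!file.exists(p)) {
          stopf("study %s: image file not found: %s", obj$study_id, p)
        }
      }
    }
    out[[i]] <- study(obj$study_id, fp, lp,
                      as.character(unlist(obj$tags)),
                      as.character(unlist(obj$report)))
  }
  out
}

resolve_path <- function(p, base) {
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

#' Load a study's image pair as matrices in [0, 1]
#' @param s an `rg_study`
#' @return list with `frontal` and `lateral` numeric matrices
#' @export
load_study_images <- function(s) {
  fr <- png::readPNG(s$frontal_path)
  la <- png::readPNG(s$lateral_path)
  if (length(dim(fr)) != 2L || length(dim(la)) != 2L) {
    stopf("study %s: images must be single-channel grayscale", s$study_id)
  }
  if (!all(dim(fr) == dim(la))) {
    stopf("study %s: frontal and lateral images differ in size", s$study_id)
  }
  list(frontal = fr, lateral = la)
}
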