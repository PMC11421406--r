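#' Matrix-test vocabulary
#'
#' A matrix sentence test draws every sentence from a fixed 5-slot
#' grammar (name - verb - number - adjective - object) with ten
#' interchangeable words per slot, 50 words in total.  A vocabulary
#' object maps each word to its unique slot.
#'
#' @param matrix a 10 x 5 character matrix (rows = alternatives,
#'   columns = slots) or a data.frame with columns `word` and `slot`.
#' @return an object of class `mt_vocabulary`: a data.frame with columns
#'   `word` and `slot` (integer 1..5), one row per word.
#' @examples
#' voc <- matrix_vocabulary()
#' nrow(voc)        # 50
#' table(voc$slot)  # 10 per slot
#' @export
matrix_vocabulary <- function(matrix = default_word_matrix()) {
  if (is.matrix(matrix)) {
    if (!all(dim(matrix) == c(10L, 5L)))
      stop_vrt("word matrix must be 10 alternatives x 5 slots")
    df <- data.frame(word = as.vector(matrix),
                     slot = rep(1:5, each = 10L),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(matrix)
    if (!all(c("word", "slot") %in% names(df)))
      stop_vrt("vocabulary data.frame needs columns 'word' and 'slot'")
    df <- df[, c("word", "slot")]
    df$slot <- as.integer(df$slot)
  }
  if (anyDuplicated(df$word))
    stop_vrt("vocabulary words must be unique (each word belongs to exactly one slot)")
  if (nrow(df) != 50L || !all(sort(unique(df$slot)) == 1:5) ||
      !all(table(df$slot) == 10L))
    stop_vrt("vocabulary must hold 10 words in each of 5 slots")
  class(df) <- c("mt_vocabulary", "data.frame")
  df
}

# German-style 10x5 word matrix (name verb number adjective object).
default_word_matrix <- function() {
  matrix(c(
    "Peter", "Kerstin", "Tanja", "Ulrich", "Britta",
    "Wolfgang", "Nina", "Stefan", "Thomas", "Doris",
    "bekommt", "sieht", "gibt", "schenkt", "kauft",
    "gewann", "nahm", "malt", "hat", "verleiht",
    "zwei", "drei", "vier", "fuenf", "sieben",
    "acht", "neun", "elf", "zwoelf", "achtzehn",
    "schoene", "kleine", "alte", "nasse", "schwere",
    "gruene", "teure", "grosse", "rote", "weisse",
    "Blumen", "Tassen", "Autos", "Bilder", "Dosen",
    "Sessel", "Messer", "Ringe", "Schuhe", "Steine"),
    nrow = 10L, ncol = 5L)
}

#' @export
print.mt_vocabulary <- function(x, ...) {
  cat("Matrix-test vocabulary: 50 words, 5 slots x 10 alternatives\n")
  invisible(x)
}

#' Out-of-vocabulary marker used in alignment records
#' @export
OOV_TOKEN <- "<OOV>"

is_oov <- function(tokens) tokens == OOV_TOKEN

slot_of <- function(words, vocabulary) {
  vocabulary$slot[match(words, vocabulary$word)]
}
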