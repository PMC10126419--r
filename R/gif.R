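# Minimal GIF89a writer used for heartbeat animations.
#
# Frames are 8-bit palette-index matrices sharing one 256-entry color table.
# The LZW stream is emitted as literal codes with a clear code before the
# dictionary would force a wider code, so every code is 9 bits; this is the
# standard "uncompressed GIF" encoding and is accepted by all decoders.

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 0xFF), bitwShiftR(x, 8)))
}

# pack a vector of 9-bit codes LSB-first into raw bytes
pack_codes9 <- function(codes) {
  n <- length(codes)
  bits <- matrix(FALSE, nrow = 9, ncol = n)
  for (b in 0:8) bits[b + 1, ] <- bitwAnd(bitwShiftR(codes, b), 1L) == 1L
  v <- as.logical(bits)
  pad <- (-length(v)) %% 8
  if (pad) v <- c(v, logical(pad))
  packBits(v, type = "raw")
}

lzw_literal_stream <- function(idx) {
  clear <- 256L; eoi <- 257L
  # a clear code every 250 literals keeps the dictionary under 512 entries
  chunks <- split(idx, ceiling(seq_along(idx) / 250))
  codes <- integer(0)
  for (ch in chunks) codes <- c(codes, clear, ch)
  codes <- c(codes, eoi)
  pack_codes9(codes)
}

sub_blocks <- function(bytes) {
  out <- raw(0)
  i <- 1L
  while (i <= length(bytes)) {
    j <- min(i + 254L, length(bytes))
    out <- c(out, as.raw(j - i + 1L), bytes[i:j])
    i <- j + 1L
  }
  c(out, as.raw(0L))
}

#' @noRd
gif_write <- function(frames_idx, palette, path, delay_cs = 10L, loop = 0L) {
  stopifnot(is.list(frames_idx), length(frames_idx) > 0,
            is.matrix(palette), nrow(palette) == 256, ncol(palette) == 3)
  d <- dim(frames_idx[[1]])
  h <- d[1]; w <- d[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF89a"), con)
  writeBin(c(u16le(w), u16le(h), as.raw(c(0xF7, 0x00, 0x00))), con)
  writeBin(as.raw(as.integer(t(palette))), con)              # global color table
  writeBin(c(as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
             as.raw(c(0x03, 0x01)), u16le(loop), as.raw(0x00)), con)
  for (f in frames_idx) {
    stopifnot(identical(dim(f), d))
    writeBin(c(as.raw(c(0x21, 0xF9, 0x04, 0x00)), u16le(delay_cs),
               as.raw(c(0x00, 0x00))), con)
    writeBin(c(as.raw(0x2C), u16le(0), u16le(0), u16le(w), u16le(h),
               as.raw(0x00), as.raw(0x08)), con)
    idx <- as.integer(t(f))                                  # row-major scan
    writeBin(sub_blocks(lzw_literal_stream(idx)), con)
  }
  writeBin(as.raw(0x3B), con)
  invisible(path)
}

# count image descriptors in a GIF file (used to verify frame counts)
#' @noRd
gif_frame_count <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  # image separator 0x2C preceded by block terminator 0x00 of the LZW data
  # or by the graphic control extension terminator; count graphic control
  # extensions instead (0x21 0xF9), one per frame as written above
  sum(bytes[-length(bytes)] == as.raw(0x21) & bytes[-1] == as.raw(0xF9))
}
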