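// Sobol low-discrepancy sequences with optional Matousek linear scrambling.
//
// Direction numbers are the standard Joe-Kuo table (first 36 dimensions,
// primitive polynomial encodings and initial m-values).  Points are
// enumerated in Gray-code order; scrambling applies, per dimension, a random
// non-singular lower-triangular binary matrix to the digit expansion plus an
// independent random digital shift.  Randomness is drawn from R's RNG so
// that set.seed() controls the scramble.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

#define SOBOL_MAXDIM 36
#define SOBOL_NBITS 32

// primitive polynomials (includes leading x^s bit and trailing constant 1)
static const uint32_t sobol_poly[SOBOL_MAXDIM] = {
  1, 3, 7, 11, 13, 19, 25, 37, 41, 47, 55, 59, 61, 67, 91, 97, 103, 109,
  115, 131, 137, 143, 145, 157, 167, 171, 185, 191, 193, 203, 211, 213,
  229, 239, 241, 247};

// initial odd direction integers m_1..m_s per dimension
static const uint32_t sobol_minit[SOBOL_MAXDIM][8] = {
  {1, 0, 0, 0, 0, 0, 0, 0}, {1, 0, 0, 0, 0, 0, 0, 0},
  {1, 3, 0, 0, 0, 0, 0, 0}, {1, 3, 1, 0, 0, 0, 0, 0},
  {1, 1, 1, 0, 0, 0, 0, 0}, {1, 1, 3, 3, 0, 0, 0, 0},
  {1, 3, 5, 13, 0, 0, 0, 0}, {1, 1, 5, 5, 17, 0, 0, 0},
  {1, 1, 5, 5, 5, 0, 0, 0}, {1, 1, 7, 11, 19, 0, 0, 0},
  {1, 1, 5, 1, 1, 0, 0, 0}, {1, 1, 1, 3, 11, 0, 0, 0},
  {1, 3, 5, 5, 31, 0, 0, 0}, {1, 3, 3, 9, 7, 49, 0, 0},
  {1, 1, 1, 15, 21, 21, 0, 0}, {1, 3, 1, 13, 27, 49, 0, 0},
  {1, 1, 1, 15, 7, 5, 0, 0}, {1, 3, 1, 15, 13, 25, 0, 0},
  {1, 1, 5, 5, 19, 61, 0, 0}, {1, 3, 7, 11, 23, 15, 103, 0},
  {1, 3, 7, 13, 13, 15, 69, 0}, {1, 1, 3, 13, 7, 35, 63, 0},
  {1, 3, 5, 9, 1, 25, 53, 0}, {1, 3, 1, 13, 9, 35, 107, 0},
  {1, 3, 1, 5, 27, 61, 31, 0}, {1, 1, 5, 11, 19, 41, 61, 0},
  {1, 3, 5, 3, 3, 13, 69, 0}, {1, 1, 7, 13, 1, 19, 1, 0},
  {1, 3, 7, 5, 13, 19, 59, 0}, {1, 1, 3, 9, 25, 29, 41, 0},
  {1, 3, 5, 13, 23, 1, 55, 0}, {1, 3, 7, 3, 13, 59, 17, 0},
  {1, 3, 1, 3, 5, 53, 69, 0}, {1, 1, 5, 5, 23, 33, 13, 0},
  {1, 1, 7, 7, 1, 61, 123, 0}, {1, 1, 7, 9, 13, 61, 49, 0}};

// fill direction numbers v[k], k = 0..nbits-1, for dimension d (0-based)
static void sobol_directions(int d, uint32_t* v) {
  if (d == 0) {  // van der Corput: v_k = 2^(nbits-k-1)
    for (int k = 0; k < SOBOL_NBITS; ++k)
      v[k] = 1u << (SOBOL_NBITS - 1 - k);
    return;
  }
  uint32_t p = sobol_poly[d];
  int s = 0;
  while ((p >> (s + 1)) != 0) ++s;  // degree of the polynomial
  for (int k = 0; k < s; ++k)
    v[k] = sobol_minit[d][k] << (SOBOL_NBITS - 1 - k);
  for (int k = s; k < SOBOL_NBITS; ++k) {
    v[k] = v[k - s] ^ (v[k - s] >> s);
    for (int i = 1; i < s; ++i)
      if ((p >> (s - i)) & 1u) v[k] ^= v[k - i];
  }
}

static uint32_t rand_bits32() {
  uint32_t x = 0;
  for (int b = 0; b < SOBOL_NBITS; ++b)
    if (unif_rand() < 0.5) x |= (1u << b);
  return x;
}

static int parity32(uint32_t x) {
  x ^= x >> 16; x ^= x >> 8; x ^= x >> 4; x ^= x >> 2; x ^= x >> 1;
  return (int)(x & 1u);
}

// [[Rcpp::export]]
NumericMatrix cpp_sobol(int n, int dim, bool scramble) {
  if (dim < 1 || dim > SOBOL_MAXDIM)
    stop("Sobol dimension must be in 1..%d", SOBOL_MAXDIM);
  if (n < 1) stop("n must be >= 1");
  NumericMatrix out(n, dim);
  std::vector<uint32_t> v(SOBOL_NBITS);
  const double scale = 1.0 / 4294967296.0;  // 2^-32
  for (int d = 0; d < dim; ++d) {
    sobol_directions(d, v.data());
    uint32_t shift = 0;
    if (scramble) {
      // random non-singular lower-triangular L: row r has forced diagonal
      // bit at digit r and random bits at digits < r (digit 0 = MSB)
      uint32_t L[SOBOL_NBITS];
      for (int r = 0; r < SOBOL_NBITS; ++r) {
        uint32_t row = 1u << (SOBOL_NBITS - 1 - r);  // diagonal
        for (int c = 0; c < r; ++c)
          if (unif_rand() < 0.5) row |= (1u << (SOBOL_NBITS - 1 - c));
        L[r] = row;
      }
      for (int k = 0; k < SOBOL_NBITS; ++k) {
        uint32_t w = 0;
        for (int r = 0; r < SOBOL_NBITS; ++r)
          if (parity32(L[r] & v[k])) w |= (1u << (SOBOL_NBITS - 1 - r));
        v[k] = w;
      }
      shift = rand_bits32();
    }
    uint32_t x = 0;
    for (int i = 0; i < n; ++i) {
      out(i, d) = (double)(x ^ shift) * scale;
      // Gray-code step: flip direction given by lowest zero bit of i
      unsigned int c = 0, ii = (unsigned int)i;
      while (ii & 1u) { ii >>= 1; ++c; }
      x ^= v[c];
    }
  }
  return out;
}
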