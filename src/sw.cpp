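// Affine-gap local alignment (Smith-Waterman / Gotoh) with two matrix fill
// orders: the classic row-major serial fill and a wavefront fill that walks
// anti-diagonals in cache-blocked bands, splitting each anti-diagonal into
// contiguous lane blocks.
//
// Matrix convention: rows index prefixes of q0 (length X), columns prefixes
// of q1 (length Y).  Z[0][.] == Z[.][0] == 0; I and J are the gap matrices
// (I consumes q1 only / horizontal, J consumes q0 only / vertical) and are
// held at an impossible value on the boundary so they never win the max.
// Lane blocks are executed one after another on a single core: the point
// of the wavefront order here is the dependency structure (any block
// schedule yields identical matrices), not thread-level speedup.
// Gap cost model: leaving Z costs gap_open for the first gapped column and
// gap_extend for each further column, i.e. a length-k gap costs
// gap_open + (k-1)*gap_extend.

#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// impossible-state surrogate; large enough headroom that subtracting
// penalties never wraps.
static const int NEG = INT_MIN / 4;

// The fills run on "masked" copies of the sequences: under the DNA
// ambiguity semantics every 'N' is replaced by a sentinel byte distinct
// per sequence, so 'N' never matches and the hot loop is a plain byte
// comparison.
static inline int subst_score(char x, char y, int match, int mismatch) {
  return x == y ? match : mismatch;
}

static void mask_n(std::string& q0, std::string& q1, bool special_n) {
  if (!special_n) return;
  for (char& c : q0)
    if (c == 'N') c = '\x01';
  for (char& c : q1)
    if (c == 'N') c = '\x02';
}

static inline void sw_cell(int a, int b, const std::string& q0,
                           const std::string& q1, int match, int mismatch,
                           int gap_open, int gap_extend, std::vector<int>& Z,
                           std::vector<int>& I, std::vector<int>& J, int W) {
  // W = Y + 1 (row stride); cell index a*W + b
  const int idx = a * W + b;
  const int up = idx - W, left = idx - 1, diag = idx - W - 1;
  int Ival = std::max(I[left] - gap_extend, Z[left] - gap_open);
  int Jval = std::max(J[up] - gap_extend, Z[up] - gap_open);
  int zv = Z[diag] + subst_score(q0[a - 1], q1[b - 1], match, mismatch);
  int best = 0;
  if (Ival > best) best = Ival;
  if (Jval > best) best = Jval;
  if (zv > best) best = zv;
  Z[idx] = best;
  I[idx] = Ival;
  J[idx] = Jval;
}

static void fill_serial(const std::string& q0, const std::string& q1,
                        int match, int mismatch, int gap_open, int gap_extend,
                        std::vector<int>& Z, std::vector<int>& I,
                        std::vector<int>& J) {
  const int X = (int)q0.size(), Y = (int)q1.size(), W = Y + 1;
  for (int a = 1; a <= X; ++a)
    for (int b = 1; b <= Y; ++b)
      sw_cell(a, b, q0, q1, match, mismatch, gap_open, gap_extend, Z, I, J,
              W);
}

// band depth of the wavefront sweep: consecutive anti-diagonals processed
// in one pass over the rows, which keeps the memory walk cache-friendly
// while preserving every cell dependency exactly (a cell is always
// computed after its left, upper and diagonal neighbours).
static const int WAVE_BAND = 256;

static void fill_wavefront(const std::string& q0, const std::string& q1,
                           int match, int mismatch, int gap_open,
                           int gap_extend, int lanes, std::vector<int>& Z,
                           std::vector<int>& I, std::vector<int>& J) {
  const int X = (int)q0.size(), Y = (int)q1.size(), W = Y + 1;
  // anti-diagonal d holds cells (a, b) with a + b == d.  All cells of one
  // anti-diagonal depend only on the two preceding anti-diagonals, so its
  // cells are independent and are dealt to `lanes` contiguous blocks.
  // Bands of WAVE_BAND consecutive anti-diagonals share one row sweep:
  // within a band, row a contributes the contiguous cells
  // b in [max(1, d0 - a), min(Y, d1 - a)], and visiting rows in ascending
  // order inside each lane block satisfies every dependency (the upper
  // neighbours of a row's band cells lie earlier in the sweep, the left
  // neighbour is the previously computed cell of the same row, and
  // everything else belongs to an earlier band).
  for (int d0 = 2; d0 <= X + Y; d0 += WAVE_BAND) {
    const int d1 = std::min(X + Y, d0 + WAVE_BAND - 1);
    const int alo = std::max(1, d0 - Y);
    const int ahi = std::min(X, d1 - 1);
    const int nrow = ahi - alo + 1;
    if (nrow <= 0) continue;
    const int nblk = std::min(lanes, nrow);
    const int blk = (nrow + nblk - 1) / nblk;
    for (int k = 0; k < nblk; ++k) {
      const int s = alo + k * blk;
      const int e = std::min(ahi, s + blk - 1);
      for (int a = s; a <= e; ++a) {
        const int blo = std::max(1, d0 - a);
        const int bhi = std::min(Y, d1 - a);
        for (int b = blo; b <= bhi; ++b)
          sw_cell(a, b, q0, q1, match, mismatch, gap_open, gap_extend, Z, I,
                  J, W);
      }
    }
  }
}

static void init_mats(int X, int Y, std::vector<int>& Z, std::vector<int>& I,
                      std::vector<int>& J) {
  const int W = Y + 1;
  Z.assign((size_t)(X + 1) * W, 0);
  I.assign((size_t)(X + 1) * W, NEG);
  J.assign((size_t)(X + 1) * W, NEG);
}

// best cell scan: row-major, strictly-greater update => smallest (row, col)
// lexicographically among ties, identically in both fill modes.
static void best_cell(const std::vector<int>& Z, int X, int Y, int& ba,
                      int& bb, int& bs) {
  const int W = Y + 1;
  ba = 0;
  bb = 0;
  bs = 0;
  for (int a = 1; a <= X; ++a)
    for (int b = 1; b <= Y; ++b)
      if (Z[a * W + b] > bs) {
        bs = Z[a * W + b];
        ba = a;
        bb = b;
      }
}

struct Backtrace {
  int q0_start, q0_end, q1_start, q1_end, score;
  std::string ops;  // run-length encoded M/I/D, I consumes q0 only
};

static std::string rle(const std::string& raw) {
  std::string out;
  size_t i = 0;
  while (i < raw.size()) {
    size_t j = i;
    while (j < raw.size() && raw[j] == raw[i]) ++j;
    out += std::to_string(j - i);
    out += raw[i];
    i = j;
  }
  return out;
}

static Backtrace backtrack(const std::vector<int>& Z, const std::vector<int>& I,
                           const std::vector<int>& J, const std::string& q0,
                           const std::string& q1, int match, int mismatch,
                           int gap_open, int gap_extend) {
  const int X = (int)q0.size(), Y = (int)q1.size(), W = Y + 1;
  int a, b, bs;
  best_cell(Z, X, Y, a, b, bs);
  Backtrace bt;
  bt.score = bs;
  bt.q0_end = a;
  bt.q1_end = b;
  if (bs == 0) {
    bt.q0_start = bt.q0_end = 0;
    bt.q1_start = bt.q1_end = 0;
    bt.ops = "";
    return bt;
  }
  std::string raw;  // ops emitted in reverse order
  int state = 0;    // 0 = Z, 1 = J (vertical, consumes q0), 2 = I (horizontal)
  while (true) {
    int idx = a * W + b;
    if (state == 0) {
      if (Z[idx] == 0) break;
      int sc = subst_score(q0[a - 1], q1[b - 1], match, mismatch);
      // precedence: diagonal > vertical (J) > horizontal (I)
      if (a > 0 && b > 0 && Z[idx] == Z[idx - W - 1] + sc) {
        raw.push_back('M');
        --a;
        --b;
      } else if (Z[idx] == J[idx]) {
        state = 1;
      } else if (Z[idx] == I[idx]) {
        state = 2;
      } else {
        stop("internal error: broken traceback at Z state");
      }
    } else if (state == 1) {
      // J[a][b] came from max(J[a-1][b] - ge, Z[a-1][b] - go); prefer closing
      raw.push_back('I');
      if (J[idx] == Z[idx - W] - gap_open) {
        state = 0;
        --a;
      } else if (J[idx] == J[idx - W] - gap_extend) {
        --a;
      } else {
        stop("internal error: broken traceback at J state");
      }
    } else {
      raw.push_back('D');
      if (I[idx] == Z[idx - 1] - gap_open) {
        state = 0;
        --b;
      } else if (I[idx] == I[idx - 1] - gap_extend) {
        --b;
      } else {
        stop("internal error: broken traceback at I state");
      }
    }
  }
  bt.q0_start = a;
  bt.q1_start = b;
  std::reverse(raw.begin(), raw.end());
  bt.ops = rle(raw);
  return bt;
}

static IntegerMatrix to_matrix(const std::vector<int>& v, int X, int Y) {
  IntegerMatrix m(X + 1, Y + 1);
  for (int a = 0; a <= X; ++a)
    for (int b = 0; b <= Y; ++b) m(a, b) = v[a * (Y + 1) + b];
  return m;
}

// [[Rcpp::export]]
List sw_fill_cpp(std::string q0, std::string q1, int match, int mismatch,
                 int gap_open, int gap_extend, bool special_n, bool wavefront,
                 int lanes) {
  if (lanes < 1) stop("lanes must be >= 1");
  const int X = (int)q0.size(), Y = (int)q1.size();
  std::vector<int> Z, I, J;
  init_mats(X, Y, Z, I, J);
  mask_n(q0, q1, special_n);
  if (X > 0 && Y > 0) {
    if (wavefront)
      fill_wavefront(q0, q1, match, mismatch, gap_open, gap_extend, lanes, Z,
                     I, J);
    else
      fill_serial(q0, q1, match, mismatch, gap_open, gap_extend, Z, I, J);
  }
  int ba, bb, bs;
  best_cell(Z, X, Y, ba, bb, bs);
  return List::create(_["Z"] = to_matrix(Z, X, Y), _["I"] = to_matrix(I, X, Y),
                      _["J"] = to_matrix(J, X, Y), _["best_score"] = bs,
                      _["best_cell"] = IntegerVector::create(ba, bb));
}

// [[Rcpp::export]]
List sw_align_cpp(std::string q0, std::string q1, int match, int mismatch,
                  int gap_open, int gap_extend, bool special_n, bool wavefront,
                  int lanes) {
  if (lanes < 1) stop("lanes must be >= 1");
  const int X = (int)q0.size(), Y = (int)q1.size();
  std::vector<int> Z, I, J;
  init_mats(X, Y, Z, I, J);
  mask_n(q0, q1, special_n);
  if (X > 0 && Y > 0) {
    if (wavefront)
      fill_wavefront(q0, q1, match, mismatch, gap_open, gap_extend, lanes, Z,
                     I, J);
    else
      fill_serial(q0, q1, match, mismatch, gap_open, gap_extend, Z, I, J);
  }
  Backtrace bt = backtrack(Z, I, J, q0, q1, match, mismatch, gap_open,
                           gap_extend);
  return List::create(
      _["score"] = bt.score,
      _["q0_interval"] = IntegerVector::create(bt.q0_start, bt.q0_end),
      _["q1_interval"] = IntegerVector::create(bt.q1_start, bt.q1_end),
      _["ops"] = bt.ops);
}

// backtrack on matrices computed by sw_fill_cpp (module API; sw_align_cpp is
// the allocation-free fast path used during seed extension).
// [[Rcpp::export]]
List sw_backtrack_cpp(IntegerMatrix Zm, IntegerMatrix Im, IntegerMatrix Jm,
                      std::string q0, std::string q1, int match, int mismatch,
                      int gap_open, int gap_extend, bool special_n) {
  const int X = (int)q0.size(), Y = (int)q1.size();
  if (Zm.nrow() != X + 1 || Zm.ncol() != Y + 1)
    stop("matrix dimensions do not match the sequences");
  std::vector<int> Z((size_t)(X + 1) * (Y + 1)), I(Z.size()), J(Z.size());
  for (int a = 0; a <= X; ++a)
    for (int b = 0; b <= Y; ++b) {
      Z[a * (Y + 1) + b] = Zm(a, b);
      I[a * (Y + 1) + b] = Im(a, b);
      J[a * (Y + 1) + b] = Jm(a, b);
    }
  mask_n(q0, q1, special_n);
  Backtrace bt = backtrack(Z, I, J, q0, q1, match, mismatch, gap_open,
                           gap_extend);
  return List::create(
      _["score"] = bt.score,
      _["q0_interval"] = IntegerVector::create(bt.q0_start, bt.q0_end),
      _["q1_interval"] = IntegerVector::create(bt.q1_start, bt.q1_end),
      _["ops"] = bt.ops);
}
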