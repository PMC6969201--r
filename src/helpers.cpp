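#include <Rcpp.h>
#include "fq_archive.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// record validation (fast single pass; returns first offending record)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cppValidateRecords(CharacterVector seq, CharacterVector qual) {
  for (R_xlen_t i = 0; i < seq.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seq, i));
    const char* q = CHAR(STRING_ELT(qual, i));
    R_xlen_t ns = LENGTH(STRING_ELT(seq, i));
    R_xlen_t nq = LENGTH(STRING_ELT(qual, i));
    if (ns != nq)
      return List::create(_["ok"] = false, _["index"] = static_cast<double>(i + 1),
                          _["reason"] = "length mismatch between sequence and quality");
    for (R_xlen_t j = 0; j < ns; ++j) {
      if (fq::baseCode(s[j]) < 0)
        return List::create(_["ok"] = false, _["index"] = static_cast<double>(i + 1),
                            _["reason"] = "sequence contains a symbol outside {A,C,G,T,N}");
      unsigned char c = static_cast<unsigned char>(q[j]);
      if (c < 33 || c > 126)
        return List::create(_["ok"] = false, _["index"] = static_cast<double>(i + 1),
                            _["reason"] = "quality character outside [33,126]");
    }
  }
  return List::create(_["ok"] = true, _["index"] = 0.0, _["reason"] = "");
}

// ---------------------------------------------------------------------------
// canonical k-mers, prefix packing, rank transform, correction rule
// ---------------------------------------------------------------------------

static std::string revcompStr(const std::string& s) {
  std::string r(s.size(), 'A');
  for (size_t i = 0; i < s.size(); ++i) {
    int c = fq::baseCode(s[s.size() - 1 - i]);
    r[i] = fq::baseChar(3 - c);
  }
  return r;
}

// [[Rcpp::export]]
CharacterVector cppCanonical(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    for (char& c : s) {
      int b = fq::baseCode(c);
      if (b < 0 || b == 4) stop("k-mer %d contains a non-ACGT symbol", (int)(i + 1));
    }
    std::string r = revcompStr(s);
    out[i] = s <= r ? s : r;
  }
  return out;
}

// [[Rcpp::export]]
double cppPackPrefix(std::string prefix) {
  if (prefix.size() > 16) stop("prefix longer than 16 bases");
  uint64_t v = 0;
  for (char c : prefix) {
    int b = fq::baseCode(c);
    if (b < 0 || b == 4) return -1.0;  // N signals the literal fallback path
    v = (v << 2) | static_cast<uint64_t>(b);
  }
  return static_cast<double>(v);
}

// [[Rcpp::export]]
IntegerVector cppRankOrder(IntegerVector counts) {
  uint32_t c[4];
  for (int i = 0; i < 4; ++i) c[i] = counts[i];
  int ord[5];
  fq::rankOrder(c, ord);
  return IntegerVector(ord, ord + 5);
}

// [[Rcpp::export]]
int cppMaybeCorrect(IntegerVector counts, int sym) {
  uint32_t c[4];
  for (int i = 0; i < 4; ++i) c[i] = counts[i];
  return fq::BaseCoder::correctionTarget(c, sym);
}

// ---------------------------------------------------------------------------
// tiered dictionaries (external pointer interface)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cppDictsNew(int e, int p, int s, int b) {
  fq::TieredDicts* d = new fq::TieredDicts();
  d->init(e, p, s, b);
  XPtr<fq::TieredDicts> xp(d, true);
  return xp;
}

// [[Rcpp::export]]
void cppDictsInsert(SEXP xp, CharacterVector seqs) {
  XPtr<fq::TieredDicts> d(xp);
  std::vector<uint8_t> codes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    fq::seqToCodes(as<std::string>(seqs[i]), codes);
    d->insertRead(codes.data(), static_cast<int>(codes.size()));
  }
}

// [[Rcpp::export]]
IntegerVector cppDictsTierSizes(SEXP xp) {
  XPtr<fq::TieredDicts> d(xp);
  return IntegerVector::create(_["e"] = d->k[0], _["p"] = d->k[1],
                               _["s"] = d->k[2], _["b"] = d->k[3]);
}

static uint64_t packCtx(const std::string& s) {
  uint64_t v = 0;
  for (char c : s) {
    int b = fq::baseCode(c);
    if (b < 0 || b == 4) stop("context must be N-free ACGT");
    v = (v << 2) | static_cast<uint64_t>(b);
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cppDictsQuery(SEXP xp, int tier, std::string context) {
  XPtr<fq::TieredDicts> d(xp);
  if (tier < 0 || tier > 3) stop("tier must be in 0..3 (e,p,s,b)");
  if (static_cast<int>(context.size()) != d->k[tier] - 1)
    stop("context length must be %d for this tier", d->k[tier] - 1);
  uint32_t out[4];
  d->d[tier].query(packCtx(context), out);
  return NumericVector::create(
      _["A"] = static_cast<double>(out[0]), _["C"] = static_cast<double>(out[1]),
      _["G"] = static_cast<double>(out[2]), _["T"] = static_cast<double>(out[3]));
}

// [[Rcpp::export]]
NumericVector cppDictsQueryPartial(SEXP xp, int tier, std::string suffix,
                                   int missing) {
  XPtr<fq::TieredDicts> d(xp);
  if (tier < 0 || tier > 3) stop("tier must be in 0..3 (e,p,s,b)");
  if (missing < 1 || missing > 2)
    stop("missing must be 1 or 2 (fall back to a smaller tier instead)");
  if (static_cast<int>(suffix.size()) + missing != d->k[tier] - 1)
    stop("length(suffix) + missing must equal %d for this tier",
         d->k[tier] - 1);
  uint32_t out[4];
  d->queryPartial(tier, packCtx(suffix), static_cast<int>(suffix.size()),
                  missing, out);
  return NumericVector::create(
      _["A"] = static_cast<double>(out[0]), _["C"] = static_cast<double>(out[1]),
      _["G"] = static_cast<double>(out[2]), _["T"] = static_cast<double>(out[3]));
}

// [[Rcpp::export]]
NumericVector cppDictsTotals(SEXP xp) {
  XPtr<fq::TieredDicts> d(xp);
  return NumericVector::create(
      _["e"] = static_cast<double>(d->d[0].totalCount()),
      _["p"] = static_cast<double>(d->d[1].totalCount()),
      _["s"] = static_cast<double>(d->d[2].totalCount()),
      _["b"] = static_cast<double>(d->d[3].totalCount()));
}

// [[Rcpp::export]]
List cppPredict(SEXP xp, std::string history) {
  XPtr<fq::TieredDicts> d(xp);
  fq::BaseCoder bc;
  bc.dicts = *d;  // copy: predict is const over dict content
  bc.e = d->k[0]; bc.p = d->k[1]; bc.s = d->k[2]; bc.b = d->k[3];
  uint64_t hist = 0;
  int lastN = -1;
  int pos = static_cast<int>(history.size());
  for (int i = 0; i < pos; ++i) {
    int c = fq::baseCode(history[i]);
    if (c < 0) stop("history contains a non-ACGTN symbol");
    if (c == 4) { lastN = i; hist <<= 2; }
    else hist = (hist << 2) | static_cast<uint64_t>(c);
  }
  fq::TierAnswer a = bc.predict(hist, pos, lastN);
  const char* tiers[5] = {"order0", "e", "p", "s", "b"};
  return List::create(
      _["tier"] = std::string(tiers[a.tier]),
      _["counts"] = NumericVector::create(
          _["A"] = static_cast<double>(a.cnt[0]),
          _["C"] = static_cast<double>(a.cnt[1]),
          _["G"] = static_cast<double>(a.cnt[2]),
          _["T"] = static_cast<double>(a.cnt[3])),
      _["missing"] = a.missing);
}

// ---------------------------------------------------------------------------
// rank model (external pointer interface)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cppRankModelNew() {
  fq::RankModelTable* m = new fq::RankModelTable();
  m->init();
  XPtr<fq::RankModelTable> xp(m, true);
  return xp;
}

static int ctxFromR(int tier, int position, IntegerVector counts,
                    bool corrPrev) {
  if (tier < 0 || tier > 4) stop("tier must be 0 (order0) .. 4 (b)");
  uint32_t c[4];
  for (int i = 0; i < 4; ++i) c[i] = counts[i];
  int ord[5];
  fq::rankOrder(c, ord);
  return fq::rankModelCtx(tier, position, c[ord[0]], c[ord[1]], corrPrev);
}

// [[Rcpp::export]]
NumericVector cppRankModelFreqs(SEXP xp, int tier, int position,
                                IntegerVector counts, bool corrPrev) {
  XPtr<fq::RankModelTable> m(xp);
  uint32_t* s = m->stats(ctxFromR(tier, position, counts, corrPrev));
  NumericVector out(5);
  for (int r = 0; r < 5; ++r) out[r] = s[r];
  return out;
}

// [[Rcpp::export]]
void cppRankModelUpdate(SEXP xp, int tier, int position, IntegerVector counts,
                        bool corrPrev, int rank) {
  XPtr<fq::RankModelTable> m(xp);
  if (rank < 0 || rank > 4) stop("rank must be in 0..4");
  m->update(ctxFromR(tier, position, counts, corrPrev), rank);
}

// ---------------------------------------------------------------------------
// minimizers and the minimizer-pair dictionary
// ---------------------------------------------------------------------------

static std::string unpackKmer(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = 0; i < k; ++i)
    s[i] = fq::baseChar(static_cast<int>((v >> (2 * (k - 1 - i))) & 3));
  return s;
}

// [[Rcpp::export]]
List cppFindMinimizer(std::string seq, int L) {
  std::vector<uint8_t> codes;
  fq::seqToCodes(seq, codes);
  uint64_t best = 0;
  int pos = -1;
  bool found = fq::findMinimizerPacked(codes.data(),
                                       static_cast<int>(codes.size()), L,
                                       best, pos);
  return List::create(_["found"] = found,
                      _["kmer"] = found ? unpackKmer(best, L) : std::string(),
                      _["position"] = pos);
}

// [[Rcpp::export]]
SEXP cppMbNew() {
  fq::MinimizerPairs* mb = new fq::MinimizerPairs();
  mb->init();
  XPtr<fq::MinimizerPairs> xp(mb, true);
  return xp;
}

// [[Rcpp::export]]
void cppMbRecord(SEXP xp, std::string m1, std::string m2) {
  XPtr<fq::MinimizerPairs> mb(xp);
  mb->record(packCtx(m1), packCtx(m2));
}

// [[Rcpp::export]]
CharacterVector cppMbCandidates(SEXP xp, std::string m1, int bLen) {
  XPtr<fq::MinimizerPairs> mb(xp);
  fq::MinimizerPairs::Entry* e = mb->find(packCtx(m1));
  if (!e) return CharacterVector(0);
  CharacterVector out(e->n);
  for (int i = 0; i < e->n; ++i) out[i] = unpackKmer(e->m2[i], bLen);
  return out;
}

// ---------------------------------------------------------------------------
// ID tokenization, quality binning / contexts
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cppTokenizeId(std::string id) {
  std::vector<fq::IdToken> toks;
  std::vector<std::string> seps;
  fq::tokenizeId(id, toks, seps);
  CharacterVector t(toks.size());
  LogicalVector num(toks.size());
  for (size_t i = 0; i < toks.size(); ++i) {
    t[i] = toks[i].text;
    num[i] = toks[i].num;
  }
  CharacterVector sp(seps.size());
  for (size_t i = 0; i < seps.size(); ++i) sp[i] = seps[i];
  return List::create(_["tokens"] = t, _["numeric"] = num,
                      _["separators"] = sp);
}

// [[Rcpp::export]]
IntegerVector cppApplyQualTable(IntegerVector q, IntegerVector sym,
                                IntegerVector rep) {
  IntegerVector out(q.size());
  for (R_xlen_t i = 0; i < q.size(); ++i) {
    if (q[i] < 0 || q[i] >= fq::QRANGE) stop("quality value out of range 0..93");
    out[i] = rep[sym[q[i]]];
  }
  return out;
}

// [[Rcpp::export]]
double cppQualContextId(int position, IntegerVector history, int mode) {
  fq::QualCodec qc;
  qc.init(mode);
  if (qc.mode == fq::QMODE_NONE) stop("no contexts in quality mode 'none'");
  uint64_t hist = 0;
  for (R_xlen_t i = 0; i < history.size(); ++i) {
    if (history[i] < 0 || history[i] >= qc.A)
      stop("history symbol out of alphabet range");
    hist = (hist * qc.A + history[i]) % qc.Ah;
  }
  return static_cast<double>(qc.ctxOf(position, hist));
}

// ---------------------------------------------------------------------------
// synthetic-data helpers (use R's RNG: deterministic under set.seed)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cppSimGenome(double length) {
  R_xlen_t n = static_cast<R_xlen_t>(length);
  std::string g(n, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    int b = static_cast<int>(unif_rand() * 4.0);
    if (b > 3) b = 3;
    g[i] = fq::baseChar(b);
  }
  return g;
}

// [[Rcpp::export]]
CharacterVector cppExtractReads(std::string genome, NumericVector start,
                                IntegerVector len, LogicalVector revcomp,
                                double errorRate) {
  R_xlen_t n = start.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t st = static_cast<R_xlen_t>(start[i]) - 1;  // 1-based input
    int L = len[i];
    buf.assign(genome, st, L);
    if (revcomp[i]) buf = revcompStr(buf);
    if (errorRate > 0) {
      int ne = static_cast<int>(R::rbinom(L, errorRate));
      for (int e = 0; e < ne; ++e) {
        int pos = static_cast<int>(unif_rand() * L);
        if (pos >= L) pos = L - 1;
        int old = fq::baseCode(buf[pos]);
        int sub = static_cast<int>(unif_rand() * 3.0);
        if (sub > 2) sub = 2;
        int nb = sub >= old ? sub + 1 : sub;  // substitution differs from old
        buf[pos] = fq::baseChar(nb);
      }
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cppSimQualities(IntegerVector len, double qStart,
                                double decay, double noiseSd, int qMin,
                                int qMax) {
  R_xlen_t n = len.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    int L = len[i];
    buf.assign(L, '!');
    for (int j = 0; j < L; ++j) {
      double q = qStart - decay * j + norm_rand() * noiseSd;
      int qi = static_cast<int>(q + 0.5);
      if (qi < qMin) qi = qMin;
      if (qi > qMax) qi = qMax;
      buf[j] = static_cast<char>(33 + qi);
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cppDistinctQuals(CharacterVector qual) {
  bool seen[fq::QRANGE] = {false};
  for (R_xlen_t i = 0; i < qual.size(); ++i) {
    const char* q = CHAR(STRING_ELT(qual, i));
    R_xlen_t n = LENGTH(STRING_ELT(qual, i));
    for (R_xlen_t j = 0; j < n; ++j) {
      int v = static_cast<unsigned char>(q[j]) - 33;
      if (v >= 0 && v < fq::QRANGE) seen[v] = true;
    }
  }
  std::vector<int> out;
  for (int v = 0; v < fq::QRANGE; ++v)
    if (seen[v]) out.push_back(v);
  return IntegerVector(out.begin(), out.end());
}

// ---------------------------------------------------------------------------
// range coder (external pointer interface for direct use and testing)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cppRcEncNew() {
  XPtr<fq::RangeEncoder> xp(new fq::RangeEncoder(), true);
  return xp;
}

static void checkCums(double cumLo, double cumHi, double total) {
  if (!(cumLo >= 0 && cumLo < cumHi && cumHi <= total &&
        total <= (1 << 24)))
    stop("require 0 <= cumLo < cumHi <= total <= 2^24");
}

// [[Rcpp::export]]
void cppRcEncSymbol(SEXP xp, double cumLo, double cumHi, double total) {
  XPtr<fq::RangeEncoder> rc(xp);
  if (rc->flushed) stop("encoder already flushed");
  checkCums(cumLo, cumHi, total);
  rc->encode(static_cast<uint32_t>(cumLo),
             static_cast<uint32_t>(cumHi - cumLo),
             static_cast<uint32_t>(total));
}

// [[Rcpp::export]]
RawVector cppRcEncFlush(SEXP xp) {
  XPtr<fq::RangeEncoder> rc(xp);
  if (rc->flushed) stop("encoder already flushed");
  rc->flush();
  RawVector out(rc->out.size());
  std::copy(rc->out.begin(), rc->out.end(), out.begin());
  return out;
}

// decoder plus an owned copy of its payload
struct RcDecHolder {
  std::vector<uint8_t> buf;
  fq::RangeDecoder rd;
};

// [[Rcpp::export]]
SEXP cppRcDecNew(RawVector bytes) {
  RcDecHolder* h = new RcDecHolder();
  h->buf.assign(bytes.begin(), bytes.end());
  h->rd.init(h->buf.data(), h->buf.size());
  XPtr<RcDecHolder> xp(h, true);
  return xp;
}

// [[Rcpp::export]]
double cppRcDecTarget(SEXP xp, double total) {
  XPtr<RcDecHolder> h(xp);
  if (!(total >= 1 && total <= (1 << 24))) stop("total must be in 1..2^24");
  return h->rd.getFreq(static_cast<uint32_t>(total));
}

// [[Rcpp::export]]
void cppRcDecUpdate(SEXP xp, double cumLo, double cumHi, double total) {
  XPtr<RcDecHolder> h(xp);
  checkCums(cumLo, cumHi, total);
  h->rd.update(static_cast<uint32_t>(cumLo),
               static_cast<uint32_t>(cumHi - cumLo));
}

// convenience bulk paths used by the optimality and round-trip tests

// [[Rcpp::export]]
RawVector cppRcEncodeStatic(IntegerVector syms, IntegerVector freqs) {
  fq::RangeEncoder rc;
  std::vector<uint32_t> cum(freqs.size() + 1, 0);
  for (int i = 0; i < freqs.size(); ++i) {
    if (freqs[i] < 1) stop("frequencies must be >= 1");
    cum[i + 1] = cum[i] + freqs[i];
  }
  if (cum.back() > (1u << 24)) stop("total exceeds 2^24");
  for (R_xlen_t i = 0; i < syms.size(); ++i) {
    int s = syms[i];
    rc.encode(cum[s], freqs[s], cum.back());
  }
  rc.flush();
  RawVector out(rc.out.size());
  std::copy(rc.out.begin(), rc.out.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
IntegerVector cppRcDecodeStatic(RawVector bytes, double n,
                                IntegerVector freqs) {
  fq::RangeDecoder rd;
  rd.init(reinterpret_cast<const uint8_t*>(RAW(bytes)), bytes.size());
  std::vector<uint32_t> cum(freqs.size() + 1, 0);
  for (int i = 0; i < freqs.size(); ++i) cum[i + 1] = cum[i] + freqs[i];
  R_xlen_t nn = static_cast<R_xlen_t>(n);
  IntegerVector out(nn);
  for (R_xlen_t i = 0; i < nn; ++i) {
    uint32_t t = rd.getFreq(cum.back());
    int s = 0;
    while (cum[s + 1] <= t) ++s;
    rd.update(cum[s], freqs[s]);
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
RawVector cppRcEncodeTables(IntegerVector syms, IntegerMatrix freqs) {
  fq::RangeEncoder rc;
  int A = freqs.ncol();
  for (R_xlen_t i = 0; i < syms.size(); ++i) {
    uint32_t lo = 0, tot = 0;
    for (int j = 0; j < A; ++j) tot += freqs(i, j);
    for (int j = 0; j < syms[i]; ++j) lo += freqs(i, j);
    rc.encode(lo, freqs(i, syms[i]), tot);
  }
  rc.flush();
  RawVector out(rc.out.size());
  std::copy(rc.out.begin(), rc.out.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
IntegerVector cppRcDecodeTables(RawVector bytes, IntegerMatrix freqs) {
  fq::RangeDecoder rd;
  rd.init(reinterpret_cast<const uint8_t*>(RAW(bytes)), bytes.size());
  int A = freqs.ncol();
  IntegerVector out(freqs.nrow());
  for (R_xlen_t i = 0; i < freqs.nrow(); ++i) {
    uint32_t tot = 0;
    for (int j = 0; j < A; ++j) tot += freqs(i, j);
    uint32_t t = rd.getFreq(tot);
    uint32_t lo = 0;
    int s = 0;
    while (lo + static_cast<uint32_t>(freqs(i, s)) <= t) {
      lo += freqs(i, s);
      ++s;
    }
    rd.update(lo, freqs(i, s));
    out[i] = s;
  }
  return out;
}
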