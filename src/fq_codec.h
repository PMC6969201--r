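#ifndef FQ_CODEC_H
#define FQ_CODEC_H

#include "fq_core.h"

namespace fq {

// ---------------------------------------------------------------------------
// Archive parameters (serialized in the header; archives are self-describing)
// ---------------------------------------------------------------------------

const int QMODE_96 = 0, QMODE_8 = 1, QMODE_4 = 2, QMODE_2 = 3, QMODE_NONE = 4;
const int IDMODE_LOSSLESS = 0, IDMODE_INSTRUMENT = 1, IDMODE_NONE = 2;
const int QRANGE = 94;  // quality characters '!'(33) .. '~'(126)

struct Params {
  bool paired = false;
  bool reo = false;
  int qualMode = QMODE_96;
  int idMode = IDMODE_LOSSLESS;
  uint64_t genomeSize = 0;
  uint64_t blockSize = 16ULL << 20;
  int e = 0, p = 0, s = 0, b = 0;
  std::vector<uint8_t> qualSym;  // QRANGE entries: score -> symbol index
  std::vector<uint8_t> qualRep;  // per symbol: representative score (0-based)

  void check() const {
    if (!(e < p && p < s && s < b) || b > 32 || e < 2)
      throw std::runtime_error("k-mer tier sizes must satisfy 1 < e < p < s < b <= 32");
    if (p > 16)
      throw std::runtime_error("p must be <= 16 (prefix packs into 2p bits)");
  }
};

// ---------------------------------------------------------------------------
// Quality-score codec: position bucket + h previous binned scores, one
// adaptive table per context.  All four context spaces are direct-indexed.
// ---------------------------------------------------------------------------

struct QualCodec {
  int mode = QMODE_NONE;
  int A = 0, h = 0, nPB = 0;
  uint64_t Ah = 1;
  std::vector<int32_t> slot;
  std::vector<AdModel> models;

  void init(int qualMode) {
    mode = qualMode;
    models.clear();
    if (mode == QMODE_NONE) return;
    static const int As[4] = {96, 8, 4, 2};
    static const int hs[4] = {2, 6, 9, 10};
    A = As[mode]; h = hs[mode];
    nPB = (mode == QMODE_96) ? 64 : 16;
    Ah = 1;
    for (int i = 0; i < h; ++i) Ah *= static_cast<uint64_t>(A);
    slot.assign(static_cast<size_t>(nPB) * Ah, -1);
  }
  size_t ctxOf(int pos, uint64_t hist) const {
    int pb = pos < nPB ? pos : nPB - 1;
    return static_cast<size_t>(pb) * Ah + hist;
  }
  AdModel& modelAt(size_t ctx) {
    int32_t& s = slot[ctx];
    if (s < 0) {
      s = static_cast<int32_t>(models.size());
      models.push_back(AdModel(A));
    }
    return models[s];
  }
  // syms: binned symbol indices of the read's quality string
  void encode(RangeEncoder& rc, const uint8_t* syms, int n) {
    uint64_t hist = 0;
    for (int i = 0; i < n; ++i) {
      modelAt(ctxOf(i, hist)).enc(rc, syms[i]);
      hist = (hist * A + syms[i]) % Ah;
    }
  }
  void decode(RangeDecoder& rc, uint8_t* syms, int n) {
    uint64_t hist = 0;
    for (int i = 0; i < n; ++i) {
      syms[i] = static_cast<uint8_t>(modelAt(ctxOf(i, hist)).dec(rc));
      hist = (hist * A + syms[i]) % Ah;
    }
  }
};

// ---------------------------------------------------------------------------
// Read-ID codec: tokenized differential coding (lossless), move-to-front
// instrument list (instrument mode), or nothing (discard mode).
// ---------------------------------------------------------------------------

inline bool isAlnumAscii(char c) {
  return (c >= '0' && c <= '9') || (c >= 'A' && c <= 'Z') ||
         (c >= 'a' && c <= 'z');
}

struct IdToken {
  bool num = false;
  long long val = 0;
  std::string text;
};

// maximal alphanumeric runs are tokens; a digit run is numeric unless it has
// a leading zero (width would be lost) or exceeds 18 digits
inline void tokenizeId(const std::string& id, std::vector<IdToken>& toks,
                       std::vector<std::string>& seps) {
  toks.clear(); seps.clear();
  size_t i = 0;
  for (;;) {
    std::string sep;
    while (i < id.size() && !isAlnumAscii(id[i])) sep += id[i++];
    seps.push_back(sep);
    if (i >= id.size()) break;
    size_t j = i;
    bool digits = true;
    while (j < id.size() && isAlnumAscii(id[j])) {
      if (id[j] < '0' || id[j] > '9') digits = false;
      ++j;
    }
    IdToken t;
    t.text = id.substr(i, j - i);
    t.num = digits && t.text.size() <= 18 &&
            (t.text.size() == 1 || t.text[0] != '0');
    if (t.num) {
      long long v = 0;
      for (char c : t.text) v = v * 10 + (c - '0');
      t.val = v;
    }
    toks.push_back(t);
    i = j;
  }
}

inline std::string firstToken(const std::string& id) {
  size_t i = 0;
  while (i < id.size() && !isAlnumAscii(id[i])) ++i;
  size_t j = i;
  while (j < id.size() && isAlnumAscii(id[j])) ++j;
  return id.substr(i, j - i);
}

const int MTF_CAP = 255;  // escape symbol = MTF_CAP

struct IdCodec {
  int mode = IDMODE_LOSSLESS;
  std::vector<IdToken> ptoks[2];
  std::vector<std::string> pseps[2];
  bool havePrev[2] = {false, false};
  AdModel structFlag, tokFlag, eqBit, byteModel, numBits, lenBits, mtfPos;
  std::vector<std::string> mtf;

  void init(int idMode) {
    mode = idMode;
    structFlag.reset(2); tokFlag.reset(2); eqBit.reset(2);
    byteModel.reset(256); numBits.reset(64); lenBits.reset(32);
    mtfPos.reset(MTF_CAP + 1);
    mtf.clear();
    havePrev[0] = havePrev[1] = false;
  }
  void blockReset() { havePrev[0] = havePrev[1] = false; }

  void encLiteralBytes(RangeEncoder& rc, const std::string& s) {
    encNumber(rc, lenBits, s.size());
    for (char c : s) byteModel.enc(rc, static_cast<uint8_t>(c));
  }
  std::string decLiteralBytes(RangeDecoder& rc) {
    size_t n = static_cast<size_t>(decNumber(rc, lenBits));
    std::string s(n, '\0');
    for (size_t i = 0; i < n; ++i)
      s[i] = static_cast<char>(byteModel.dec(rc));
    return s;
  }

  void encodeInstrument(RangeEncoder& rc, const std::string& id) {
    std::string name = firstToken(id);
    int pos = -1;
    for (size_t i = 0; i < mtf.size(); ++i)
      if (mtf[i] == name) { pos = static_cast<int>(i); break; }
    if (pos >= 0) {
      mtfPos.enc(rc, pos);
      mtf.erase(mtf.begin() + pos);
    } else {
      mtfPos.enc(rc, MTF_CAP);
      encLiteralBytes(rc, name);
      if (mtf.size() >= MTF_CAP) mtf.pop_back();
    }
    mtf.insert(mtf.begin(), name);
  }
  std::string decodeInstrument(RangeDecoder& rc) {
    int pos = mtfPos.dec(rc);
    std::string name;
    if (pos < MTF_CAP && pos < static_cast<int>(mtf.size())) {
      name = mtf[pos];
      mtf.erase(mtf.begin() + pos);
    } else {
      name = decLiteralBytes(rc);
      if (mtf.size() >= MTF_CAP) mtf.pop_back();
    }
    mtf.insert(mtf.begin(), name);
    return name;
  }

  void encodeLossless(RangeEncoder& rc, int mate, const std::string& id,
                      bool forceLiteral) {
    std::vector<IdToken> toks;
    std::vector<std::string> seps;
    fq::tokenizeId(id, toks, seps);
    bool match = !forceLiteral && havePrev[mate] &&
                 toks.size() == ptoks[mate].size() &&
                 seps.size() == pseps[mate].size();
    if (match) {
      for (size_t i = 0; i < seps.size() && match; ++i)
        if (seps[i] != pseps[mate][i]) match = false;
      for (size_t i = 0; i < toks.size() && match; ++i)
        if (toks[i].num != ptoks[mate][i].num) match = false;
    }
    structFlag.enc(rc, match ? 0 : 1);
    if (match) {
      for (size_t i = 0; i < toks.size(); ++i) {
        const IdToken& c = toks[i];
        const IdToken& pv = ptoks[mate][i];
        if (c.num) {
          encNumber(rc, numBits, zigzag(c.val - pv.val));
        } else if (c.text == pv.text) {
          tokFlag.enc(rc, 0);
        } else {
          tokFlag.enc(rc, 1);
          encNumber(rc, lenBits, c.text.size());
          for (size_t j = 0; j < c.text.size(); ++j) {
            if (j < pv.text.size()) {
              bool same = c.text[j] == pv.text[j];
              eqBit.enc(rc, same ? 0 : 1);
              if (!same) byteModel.enc(rc, static_cast<uint8_t>(c.text[j]));
            } else {
              byteModel.enc(rc, static_cast<uint8_t>(c.text[j]));
            }
          }
        }
      }
    } else {
      encLiteralBytes(rc, id);
    }
    ptoks[mate] = std::move(toks);
    pseps[mate] = std::move(seps);
    havePrev[mate] = true;
  }

  std::string decodeLossless(RangeDecoder& rc, int mate) {
    std::string id;
    int literal = structFlag.dec(rc);
    if (literal) {
      id = decLiteralBytes(rc);
      fq::tokenizeId(id, ptoks[mate], pseps[mate]);
    } else {
      std::vector<IdToken>& pt = ptoks[mate];
      std::vector<std::string>& ps = pseps[mate];
      for (size_t i = 0; i < pt.size(); ++i) {
        IdToken& t = pt[i];
        if (t.num) {
          t.val += unzigzag(decNumber(rc, numBits));
          t.text = std::to_string(t.val);
        } else if (tokFlag.dec(rc) == 1) {
          size_t n = static_cast<size_t>(decNumber(rc, lenBits));
          std::string nt(n, '\0');
          for (size_t j = 0; j < n; ++j) {
            if (j < t.text.size()) {
              if (eqBit.dec(rc) == 0) nt[j] = t.text[j];
              else nt[j] = static_cast<char>(byteModel.dec(rc));
            } else {
              nt[j] = static_cast<char>(byteModel.dec(rc));
            }
          }
          t.text = nt;
        }
      }
      for (size_t i = 0; i < ps.size(); ++i) {
        id += ps[i];
        if (i < pt.size()) id += pt[i].text;
      }
    }
    havePrev[mate] = true;
    return id;
  }
};

// ---------------------------------------------------------------------------
// Base codec: tier-cascade prediction, rank transform under the adaptive
// rank model, synchronized in-stream correction, REO prefix delta coding.
// ---------------------------------------------------------------------------

struct TierAnswer {
  int tier = 0;  // 0 = order-0 fallback, 1..4 = e,p,s,b
  uint32_t cnt[4] = {0, 0, 0, 0};
  int missing = 0;
};

const int MAX_CORRECTIONS_PER_READ = 8;

struct BaseCoder {
  TieredDicts dicts;
  RankModelTable rank;
  AdModel order0[16];
  AdModel lenBits;
  AdModel prefEscape, prefBits;
  int e = 0, p = 0, s = 0, b = 0;
  int64_t prevLen[2] = {0, 0};
  uint32_t prevPrefix = 0;
  uint64_t nCorrections = 0;

  void init(const Params& P) {
    e = P.e; p = P.p; s = P.s; b = P.b;
    dicts.init(e, p, s, b);
    rank.init();
    for (int i = 0; i < 16; ++i) order0[i].reset(5);
    lenBits.reset(40);
    prefEscape.reset(2);
    prefBits.reset(2 * p + 2);
    blockReset();
  }
  void blockReset() {
    prevLen[0] = prevLen[1] = 0;
    prevPrefix = 0;
  }

  TierAnswer predict(uint64_t hist, int pos, int lastN) const {
    TierAnswer ans;  // order-0 default
    if (pos < e - 1) return ans;
    TierAnswer smallest;
    bool haveUsable = false;
    for (int t = 3; t >= 0; --t) {
      int c = dicts.k[t] - 1;
      TierAnswer cur;
      if (c <= pos) {
        if (lastN >= pos - c) continue;  // N inside the context
        dicts.d[t].query(hist & kmask(c), cur.cnt);
        cur.missing = 0;
      } else if (c - pos <= 2) {
        if (lastN >= 0) continue;  // whole history needed, must be N-free
        dicts.queryPartial(t, hist & kmask(pos), pos, c - pos, cur.cnt);
        cur.missing = c - pos;
      } else {
        continue;
      }
      cur.tier = t + 1;
      if (cur.cnt[0] | cur.cnt[1] | cur.cnt[2] | cur.cnt[3]) return cur;
      smallest = cur;
      haveUsable = true;
    }
    return haveUsable ? smallest : ans;
  }

  // error-correction rule: current count 0, unique maximum >= 3
  static int correctionTarget(const uint32_t cnt[4], int sym) {
    if (sym == 4 || cnt[sym] != 0) return sym;
    uint32_t mx = 0;
    int arg = -1, nmx = 0;
    for (int x = 0; x < 4; ++x) {
      if (cnt[x] > mx) { mx = cnt[x]; arg = x; nmx = 1; }
      else if (cnt[x] == mx && mx > 0) ++nmx;
    }
    if (mx >= 3 && nmx == 1) return arg;
    return sym;
  }

  // Encode or decode the bases of one read.  `orig` holds the emitted
  // symbols (input on encode, output on decode); `work` receives the
  // corrected sequence used for contexts and dictionary insertion.
  // Positions < from, or inside [knownFrom, knownTo), are taken as given
  // (REO prefix / PE predicted b-mer) and are not entropy-coded.
  template <bool ENC>
  void codeReadBases(RangeEncoder* re, RangeDecoder* rd, uint8_t* orig,
                     uint8_t* work, int len, int from, int knownFrom = -1,
                     int knownTo = -1) {
    uint64_t hist = 0;
    int lastN = -1;
    bool corrPrev = false;
    int ncorr = 0;
    for (int i = 0; i < len; ++i) {
      bool coded = i >= from && !(i >= knownFrom && i < knownTo);
      int sym;
      TierAnswer a;
      if (coded) {
        a = predict(hist, i, lastN);
        if (a.tier == 0) {
          AdModel& m = order0[i < 15 ? i : 15];
          if (ENC) { sym = orig[i]; m.enc(*re, sym); }
          else { sym = m.dec(*rd); orig[i] = static_cast<uint8_t>(sym); }
        } else {
          int ord[5];
          rankOrder(a.cnt, ord);
          int ctx = rankModelCtx(a.tier, i, a.cnt[ord[0]], a.cnt[ord[1]],
                                 corrPrev);
          if (ENC) {
            sym = orig[i];
            int r = 4;
            if (sym != 4)
              for (int k2 = 0; k2 < 4; ++k2)
                if (ord[k2] == sym) { r = k2; break; }
            rank.enc(*re, ctx, r);
          } else {
            int r = rank.dec(*rd, ctx);
            sym = ord[r];
            orig[i] = static_cast<uint8_t>(sym);
          }
        }
      } else {
        sym = orig[i];
      }
      int w = sym;
      if (coded && a.tier == 4 && ncorr < MAX_CORRECTIONS_PER_READ) {
        w = correctionTarget(a.cnt, sym);
        if (w != sym) { ++ncorr; ++nCorrections; }
      }
      work[i] = static_cast<uint8_t>(w);
      corrPrev = (w != sym);
      if (w == 4) { lastN = i; hist <<= 2; }
      else hist = (hist << 2) | static_cast<uint64_t>(w);
    }
  }

  void encodeLength(RangeEncoder& rc, int mate, int len) {
    encNumber(rc, lenBits, zigzag(len - prevLen[mate]));
    prevLen[mate] = len;
  }
  int decodeLength(RangeDecoder& rc, int mate) {
    int64_t len = prevLen[mate] + unzigzag(decNumber(rc, lenBits));
    if (len < 0 || len > 0x7FFFFFFF)
      throw std::runtime_error("corrupt archive: bad read length");
    prevLen[mate] = len;
    return static_cast<int>(len);
  }

  void digest(Fnv64& d) const {
    dicts.digest(d);
    rank.digest(d);
    for (int i = 0; i < 16; ++i)
      d.add(order0[i].f.data(), order0[i].f.size() * 4);
  }
};

// ---------------------------------------------------------------------------
// Byte-stream serialization helpers (little-endian)
// ---------------------------------------------------------------------------

struct ByteWriter {
  std::vector<uint8_t> v;
  void u8(uint8_t x) { v.push_back(x); }
  void u32(uint32_t x) { for (int i = 0; i < 4; ++i) v.push_back((x >> (8 * i)) & 0xFF); }
  void u64(uint64_t x) { for (int i = 0; i < 8; ++i) v.push_back((x >> (8 * i)) & 0xFF); }
  void bytes(const uint8_t* p, size_t n) { v.insert(v.end(), p, p + n); }
};

struct ByteReader {
  const uint8_t* p;
  size_t n, pos = 0;
  ByteReader(const uint8_t* p_, size_t n_) : p(p_), n(n_) {}
  void need(size_t k) const {
    if (pos + k > n) throw std::runtime_error("truncated archive");
  }
  uint8_t u8() { need(1); return p[pos++]; }
  uint32_t u32() {
    need(4);
    uint32_t x = 0;
    for (int i = 0; i < 4; ++i) x |= static_cast<uint32_t>(p[pos++]) << (8 * i);
    return x;
  }
  uint64_t u64() {
    need(8);
    uint64_t x = 0;
    for (int i = 0; i < 8; ++i) x |= static_cast<uint64_t>(p[pos++]) << (8 * i);
    return x;
  }
};

}  // namespace fq

#endif
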