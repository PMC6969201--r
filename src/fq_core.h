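#ifndef FQ_CORE_H
#define FQ_CORE_H

#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>
#include <stdexcept>

namespace fq {

// ---------------------------------------------------------------------------
// DNA symbol codes: A=0, C=1, G=2, T=3, N=4.  2-bit packing is big-endian
// (first base in the highest bits) so packed order equals lexicographic order.
// ---------------------------------------------------------------------------

inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    case 'N': return 4;
    default:  return -1;
  }
}

inline char baseChar(int c) { return "ACGTN"[c]; }

// reverse complement of a 2k-bit packed k-mer (no N)
inline uint64_t rcPacked(uint64_t v, int k) {
  v = ~v;
  v = ((v & 0x3333333333333333ULL) << 2) | ((v >> 2) & 0x3333333333333333ULL);
  v = ((v & 0x0F0F0F0F0F0F0F0FULL) << 4) | ((v >> 4) & 0x0F0F0F0F0F0F0F0FULL);
#if defined(__GNUC__) || defined(__clang__)
  v = __builtin_bswap64(v);
#else
  {
    uint64_t r = 0;
    for (int i = 0; i < 8; ++i) { r = (r << 8) | (v & 0xFF); v >>= 8; }
    v = r;
  }
#endif
  return v >> (64 - 2 * k);
}

inline uint64_t kmask(int k) {  // mask of 2k low bits
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// FNV-1a 64-bit, used for block checksums and state digests
struct Fnv64 {
  uint64_t h = 1469598103934665603ULL;
  void add(const void* p, size_t n) {
    const uint8_t* b = static_cast<const uint8_t*>(p);
    for (size_t i = 0; i < n; ++i) { h ^= b[i]; h *= 1099511628211ULL; }
  }
  void u8(uint8_t v)   { add(&v, 1); }
  void u32(uint32_t v) { add(&v, 4); }
  void u64(uint64_t v) { add(&v, 8); }
};

// ---------------------------------------------------------------------------
// Byte-oriented range coder: 32-bit range, 64-bit low with carry propagation
// through a cached byte run, renormalization when range < 2^24.  Cumulative
// totals must stay <= 2^24 so range/total never becomes zero.
// ---------------------------------------------------------------------------

const uint32_t RC_TOP = 1u << 24;

struct RangeEncoder {
  uint64_t low = 0;
  uint32_t range = 0xFFFFFFFFu;
  uint8_t cache = 0;
  int64_t cacheSize = 1;
  bool flushed = false;
  std::vector<uint8_t> out;

  void shiftLow() {
    if (static_cast<uint32_t>(low) < 0xFF000000u || (low >> 32) != 0) {
      uint8_t carry = static_cast<uint8_t>(low >> 32);
      uint8_t t = cache;
      do {
        out.push_back(static_cast<uint8_t>(t + carry));
        t = 0xFF;
      } while (--cacheSize != 0);
      cache = static_cast<uint8_t>(static_cast<uint32_t>(low) >> 24);
    }
    ++cacheSize;
    low = static_cast<uint64_t>(static_cast<uint32_t>(low) << 8);
  }

  void encode(uint32_t cumLo, uint32_t freq, uint32_t total) {
    range /= total;
    low += static_cast<uint64_t>(cumLo) * range;
    range *= freq;
    while (range < RC_TOP) { range <<= 8; shiftLow(); }
  }

  void encodeBits(uint64_t value, int nbits) {  // raw bits, MSB first
    while (nbits > 0) {
      int nb = nbits > 16 ? 16 : nbits;
      uint32_t chunk =
          static_cast<uint32_t>((value >> (nbits - nb)) & ((1u << nb) - 1u));
      encode(chunk, 1, 1u << nb);
      nbits -= nb;
    }
  }

  void flush() {
    for (int i = 0; i < 5; ++i) shiftLow();
    flushed = true;
  }
};

struct RangeDecoder {
  const uint8_t* buf = nullptr;
  size_t n = 0, pos = 0;
  uint32_t range = 0xFFFFFFFFu;
  uint32_t code = 0;

  void init(const uint8_t* b, size_t len) {
    buf = b; n = len; pos = 0;
    range = 0xFFFFFFFFu; code = 0;
    for (int i = 0; i < 5; ++i) code = (code << 8) | nextByte();
  }
  uint8_t nextByte() { return pos < n ? buf[pos++] : 0; }

  // returns scaled cumulative count in [0, total); range is pre-divided here
  uint32_t getFreq(uint32_t total) {
    uint32_t v = code / (range /= total);
    return v >= total ? total - 1 : v;
  }
  void update(uint32_t cumLo, uint32_t freq) {
    code -= cumLo * range;
    range *= freq;
    while (range < RC_TOP) { code = (code << 8) | nextByte(); range <<= 8; }
  }
  uint64_t decodeBits(int nbits) {
    uint64_t v = 0;
    while (nbits > 0) {
      int nb = nbits > 16 ? 16 : nbits;
      uint32_t t = getFreq(1u << nb);
      update(t, 1);
      v = (v << nb) | t;
      nbits -= nb;
    }
    return v;
  }
};

// ---------------------------------------------------------------------------
// Adaptive frequency table: additive increment with periodic halving.
// Same scheme everywhere (increment 32, rescale above 2^16, floor 1).
// ---------------------------------------------------------------------------

const uint32_t AD_INC = 32;
const uint32_t AD_MAX = 1u << 16;

struct AdModel {
  std::vector<uint32_t> f;
  uint32_t tot = 0;

  AdModel() {}
  explicit AdModel(int nsym, uint32_t init = 1) { reset(nsym, init); }
  void reset(int nsym, uint32_t init = 1) {
    f.assign(nsym, init);
    tot = static_cast<uint32_t>(nsym) * init;
  }
  void bump(int s) {
    f[s] += AD_INC; tot += AD_INC;
    if (tot > AD_MAX) rescale();
  }
  void rescale() {
    tot = 0;
    for (auto& v : f) { v = (v + 1) >> 1; tot += v; }
  }
  void enc(RangeEncoder& rc, int s) {
    uint32_t lo = 0;
    for (int i = 0; i < s; ++i) lo += f[i];
    rc.encode(lo, f[s], tot);
    bump(s);
  }
  int dec(RangeDecoder& rc) {
    uint32_t t = rc.getFreq(tot);
    uint32_t lo = 0; int s = 0;
    while (lo + f[s] <= t) { lo += f[s]; ++s; }
    rc.update(lo, f[s]);
    bump(s);
    return s;
  }
};

inline uint64_t zigzag(int64_t v) {
  return (static_cast<uint64_t>(v) << 1) ^ static_cast<uint64_t>(v >> 63);
}
inline int64_t unzigzag(uint64_t z) {
  return static_cast<int64_t>(z >> 1) ^ -static_cast<int64_t>(z & 1);
}
inline int bitlen(uint64_t v) {
  int b = 0;
  while (v) { ++b; v >>= 1; }
  return b;
}

// number coded as bit-length symbol + raw lower bits (MSB implicit)
inline void encNumber(RangeEncoder& rc, AdModel& blm, uint64_t v) {
  int b = bitlen(v);
  blm.enc(rc, b);
  if (b > 1) rc.encodeBits(v & ((1ULL << (b - 1)) - 1), b - 1);
}
inline uint64_t decNumber(RangeDecoder& rc, AdModel& blm) {
  int b = blm.dec(rc);
  if (b == 0) return 0;
  if (b == 1) return 1;
  return (1ULL << (b - 1)) | rc.decodeBits(b - 1);
}

// ---------------------------------------------------------------------------
// Successor-count dictionary for one k-mer tier.  Open addressing with linear
// probing; key = packed (k-1)-mer context of the canonical k-mer, value =
// saturating counts of its four successors.
// ---------------------------------------------------------------------------

const uint64_t DICT_EMPTY = ~0ULL;
const uint16_t CNT_CAP = 0xFFFF;

struct KmerDict {
  int k = 0;  // full k-mer length; context is k-1 bases
  std::vector<uint64_t> keys;
  std::vector<uint16_t> cnt;  // 4 per slot
  size_t cap = 0, used = 0;
  uint64_t mask = 0;

  void init(int k_, size_t cap0 = 1u << 12) {
    k = k_;
    cap = cap0; mask = cap - 1;
    keys.assign(cap, DICT_EMPTY);
    cnt.assign(cap * 4, 0);
    used = 0;
  }
  size_t slotOf(uint64_t key) const {
    size_t h = splitmix64(key) & mask;
    while (keys[h] != DICT_EMPTY && keys[h] != key) h = (h + 1) & mask;
    return h;
  }
  const uint16_t* find(uint64_t key) const {
    size_t h = slotOf(key);
    return keys[h] == key ? &cnt[4 * h] : nullptr;
  }
  void grow() {
    std::vector<uint64_t> ok; ok.swap(keys);
    std::vector<uint16_t> oc; oc.swap(cnt);
    size_t ocap = cap;
    cap <<= 1; mask = cap - 1;
    keys.assign(cap, DICT_EMPTY);
    cnt.assign(cap * 4, 0);
    for (size_t i = 0; i < ocap; ++i) {
      if (ok[i] == DICT_EMPTY) continue;
      size_t h = slotOf(ok[i]);
      keys[h] = ok[i];
      std::memcpy(&cnt[4 * h], &oc[4 * i], 4 * sizeof(uint16_t));
    }
  }
  void bump(uint64_t key, int succ) {
    size_t h = slotOf(key);
    if (keys[h] == DICT_EMPTY) {
      if ((used + 1) * 5 >= cap * 3) { grow(); h = slotOf(key); }
      keys[h] = key;
      ++used;
    }
    uint16_t& c = cnt[4 * h + succ];
    if (c < CNT_CAP) ++c;
  }
  // counts of the four possible successors of a (k-1)-mer context, resolving
  // each candidate k-mer through its canonical orientation
  void query(uint64_t ctx, uint32_t out[4]) const {
    uint64_t rcc = rcPacked(ctx, k - 1);
    const uint16_t* fwd = nullptr;
    bool fwdLooked = false;
    int shift = 2 * (k - 1);
    for (int x = 0; x < 4; ++x) {
      uint64_t f = (ctx << 2) | static_cast<uint64_t>(x);
      uint64_t r = (static_cast<uint64_t>(3 - x) << shift) | rcc;
      if (f <= r) {
        if (!fwdLooked) { fwd = find(ctx); fwdLooked = true; }
        out[x] = fwd ? fwd[x] : 0;
      } else {
        const uint16_t* e = find(r >> 2);
        out[x] = e ? e[r & 3] : 0;
      }
    }
  }
  void digest(Fnv64& d) const {
    for (size_t i = 0; i < cap; ++i) {
      if (keys[i] == DICT_EMPTY) continue;
      d.u64(keys[i]);
      d.add(&cnt[4 * i], 4 * sizeof(uint16_t));
    }
  }
  uint64_t totalCount() const {
    uint64_t t = 0;
    for (size_t i = 0; i < cap; ++i)
      if (keys[i] != DICT_EMPTY)
        for (int x = 0; x < 4; ++x) t += cnt[4 * i + x];
    return t;
  }
};

// The four tiers, ascending: index 0..3 = e, p, s, b.
struct TieredDicts {
  int k[4] = {0, 0, 0, 0};
  KmerDict d[4];

  void init(int e, int p, int s, int b) {
    int kk[4] = {e, p, s, b};
    for (int t = 0; t < 4; ++t) { k[t] = kk[t]; d[t].init(kk[t]); }
  }
  // count every N-free k-mer of the read once, under canonical orientation
  void insertRead(const uint8_t* seq, int n) {
    uint64_t fwd[4] = {0, 0, 0, 0}, rev[4] = {0, 0, 0, 0};
    int lastN = -1;
    for (int i = 0; i < n; ++i) {
      int c = seq[i];
      if (c == 4) { lastN = i; c = 0; }
      for (int t = 0; t < 4; ++t) {
        int kk = k[t];
        fwd[t] = ((fwd[t] << 2) | static_cast<uint64_t>(c)) & kmask(kk);
        rev[t] = (rev[t] >> 2) |
                 (static_cast<uint64_t>(3 - c) << (2 * (kk - 1)));
        if (i >= kk - 1 && lastN < i - kk + 1) {
          uint64_t cf = fwd[t], cr = rev[t];
          if (cf <= cr) d[t].bump(cf >> 2, static_cast<int>(cf & 3));
          else          d[t].bump(cr >> 2, static_cast<int>(cr & 3));
        }
      }
    }
  }
  // sum of exact queries over all completions of `missing` leading symbols;
  // suffix holds `suffixLen` packed bases (low bits = most recent)
  void queryPartial(int t, uint64_t suffix, int suffixLen, int missing,
                    uint32_t out[4]) const {
    out[0] = out[1] = out[2] = out[3] = 0;
    int nExp = 1 << (2 * missing);
    uint32_t tmp[4];
    for (int pre = 0; pre < nExp; ++pre) {
      uint64_t ctx = (static_cast<uint64_t>(pre) << (2 * suffixLen)) | suffix;
      d[t].query(ctx, tmp);
      for (int x = 0; x < 4; ++x) {
        uint64_t sum = static_cast<uint64_t>(out[x]) + tmp[x];
        out[x] = sum > 0xFFFFFFFFULL ? 0xFFFFFFFFu : static_cast<uint32_t>(sum);
      }
    }
  }
  void digest(Fnv64& dg) const {
    for (int t = 0; t < 4; ++t) d[t].digest(dg);
  }
};

// ---------------------------------------------------------------------------
// Rank order and the adaptive rank model ("Model" dictionary).
// ---------------------------------------------------------------------------

// stable order of bases 0..3 by descending count, ties lexicographic; N last
inline void rankOrder(const uint32_t cnt[4], int order[5]) {
  order[0] = 0; order[1] = 1; order[2] = 2; order[3] = 3;
  for (int i = 1; i < 4; ++i) {        // insertion sort, stable
    int v = order[i]; uint32_t cv = cnt[v];
    int j = i - 1;
    while (j >= 0 && cnt[order[j]] < cv) { order[j + 1] = order[j]; --j; }
    order[j + 1] = v;
  }
  order[4] = 4;
}

// context descriptor -> index into the dense model table (13 bits)
// tier: 0 = order-0 fallback, 1..4 = e..b
inline int rankModelCtx(int tier, int pos, uint32_t c0, uint32_t c1,
                        bool corrPrev) {
  int pb = pos < 15 ? pos : 15;
  int q1;
  if (c0 == 0) q1 = 0;
  else if (c0 == 1) q1 = 1;
  else if (c0 == 2) q1 = 2;
  else if (c0 <= 4) q1 = 3;
  else if (c0 <= 16) q1 = 4;
  else q1 = 5;
  int q2;
  if (c0 == 0 || c1 == 0) q2 = 0;
  else if (4 * c1 <= c0) q2 = 1;
  else if (2 * c1 <= c0) q2 = 2;
  else q2 = 3;
  return tier | (pb << 3) | (q1 << 7) | (q2 << 10) | ((corrPrev ? 1 : 0) << 12);
}

const int RANK_CTXS = 1 << 13;
const uint32_t RANK_INIT[5] = {16, 8, 4, 2, 1};

struct RankModelTable {
  std::vector<uint32_t> f;  // RANK_CTXS * 5

  void init(const uint32_t* ini = RANK_INIT) {
    f.resize(RANK_CTXS * 5);
    for (int c = 0; c < RANK_CTXS; ++c)
      for (int r = 0; r < 5; ++r) f[5 * c + r] = ini[r];
  }
  uint32_t* stats(int ctx) { return &f[5 * ctx]; }
  void update(int ctx, int rank) {
    uint32_t* s = stats(ctx);
    s[rank] += AD_INC;
    uint32_t tot = s[0] + s[1] + s[2] + s[3] + s[4];
    if (tot > AD_MAX)
      for (int r = 0; r < 5; ++r) s[r] = (s[r] + 1) >> 1;
  }
  void enc(RangeEncoder& rc, int ctx, int rank) {
    uint32_t* s = stats(ctx);
    uint32_t tot = s[0] + s[1] + s[2] + s[3] + s[4];
    uint32_t lo = 0;
    for (int r = 0; r < rank; ++r) lo += s[r];
    rc.encode(lo, s[rank], tot);
    update(ctx, rank);
  }
  int dec(RangeDecoder& rc, int ctx) {
    uint32_t* s = stats(ctx);
    uint32_t tot = s[0] + s[1] + s[2] + s[3] + s[4];
    uint32_t t = rc.getFreq(tot);
    uint32_t lo = 0; int r = 0;
    while (lo + s[r] <= t) { lo += s[r]; ++r; }
    rc.update(lo, s[r]);
    update(ctx, r);
    return r;
  }
  void digest(Fnv64& d) const { d.add(f.data(), f.size() * 4); }
};

// ---------------------------------------------------------------------------
// Minimizer-pair dictionary M_b: first-read minimizer -> counted, descending-
// sorted list of second-read b-mers (canonical, capped).
// ---------------------------------------------------------------------------

const int MB_CAP = 8;

struct MinimizerPairs {
  struct Entry {
    uint64_t m1;
    uint64_t m2[MB_CAP];
    uint32_t c[MB_CAP];
    int n;
  };
  std::vector<Entry> entries;
  std::vector<int32_t> table;  // open addressing -> index into entries
  size_t cap = 0;
  uint64_t mask = 0;

  void init(size_t cap0 = 1u << 12) {
    cap = cap0; mask = cap - 1;
    table.assign(cap, -1);
    entries.clear();
  }
  size_t slotOf(uint64_t key) const {
    size_t h = splitmix64(key) & mask;
    while (table[h] >= 0 && entries[table[h]].m1 != key) h = (h + 1) & mask;
    return h;
  }
  void grow() {
    cap <<= 1; mask = cap - 1;
    table.assign(cap, -1);
    for (size_t i = 0; i < entries.size(); ++i) {
      size_t h = slotOf(entries[i].m1);
      table[h] = static_cast<int32_t>(i);
    }
  }
  Entry* find(uint64_t m1) {
    size_t h = slotOf(m1);
    return table[h] >= 0 ? &entries[table[h]] : nullptr;
  }
  void record(uint64_t m1, uint64_t m2) {
    size_t h = slotOf(m1);
    if (table[h] < 0) {
      if ((entries.size() + 1) * 5 >= cap * 3) { grow(); h = slotOf(m1); }
      table[h] = static_cast<int32_t>(entries.size());
      entries.push_back(Entry());
      Entry& e = entries.back();
      e.m1 = m1; e.n = 0;
    }
    Entry& e = entries[table[h]];
    for (int i = 0; i < e.n; ++i) {
      if (e.m2[i] == m2) {
        ++e.c[i];
        while (i > 0 && e.c[i] > e.c[i - 1]) {  // ties keep earlier entry first
          std::swap(e.c[i], e.c[i - 1]);
          std::swap(e.m2[i], e.m2[i - 1]);
          --i;
        }
        return;
      }
    }
    if (e.n < MB_CAP) {
      e.m2[e.n] = m2; e.c[e.n] = 1; ++e.n;
    } else {  // evict the lowest-count (last) candidate
      e.m2[MB_CAP - 1] = m2; e.c[MB_CAP - 1] = 1;
    }
  }
  void digest(Fnv64& d) const {
    for (const Entry& e : entries) {
      d.u64(e.m1);
      for (int i = 0; i < e.n; ++i) { d.u64(e.m2[i]); d.u32(e.c[i]); }
    }
  }
};

// smallest canonical L-mer over all N-free windows; leftmost on ties.
// returns false when no N-free window exists.
inline bool findMinimizerPacked(const uint8_t* seq, int n, int L,
                                uint64_t& best, int& bestPos) {
  if (n < L) return false;
  uint64_t fwd = 0, rev = 0;
  int lastN = -1;
  bool found = false;
  for (int i = 0; i < n; ++i) {
    int c = seq[i];
    if (c == 4) { lastN = i; c = 0; }
    fwd = ((fwd << 2) | static_cast<uint64_t>(c)) & kmask(L);
    rev = (rev >> 2) | (static_cast<uint64_t>(3 - c) << (2 * (L - 1)));
    if (i >= L - 1 && lastN < i - L + 1) {
      uint64_t cand = fwd <= rev ? fwd : rev;
      if (!found || cand < best) { best = cand; bestPos = i - L + 1; found = true; }
    }
  }
  return found;
}

}  // namespace fq

#endif
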