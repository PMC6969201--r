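#ifndef FQ_ARCHIVE_H
#define FQ_ARCHIVE_H

#include "fq_codec.h"

namespace fq {

// stream indices within a block
enum { ST_BASES = 0, ST_LEN = 1, ST_IDS = 2, ST_QUAL = 3, ST_PE = 4,
       ST_PREF = 5, N_STREAMS = 6 };

const char MAGIC[4] = {'F', 'Q', 'P', 'K'};
const uint8_t FORMAT_VERSION = 1;
const char QUAL_PLACEHOLDER = 'I';  // emitted in quality mode "none"

// Shared encoder/decoder machine: decompression replays exactly the
// prediction/update/correction work of compression.
struct Engine {
  Params P;
  BaseCoder base;
  QualCodec qual;
  IdCodec id;
  MinimizerPairs mb;
  AdModel peRank, pePosBits, peOrient;
  uint64_t unitCounter = 0;
  uint64_t peHit = 0, peMiss = 0;

  void init() {
    P.check();
    base.init(P);
    qual.init(P.qualMode);
    id.init(P.idMode);
    mb.init();
    peRank.reset(MB_CAP + 1);
    pePosBits.reset(34);
    peOrient.reset(2);
    unitCounter = 0;
    peHit = peMiss = 0;
  }
  uint64_t digest() const {
    Fnv64 d;
    base.digest(d);
    mb.digest(d);
    return d.h;
  }
};

inline void seqToCodes(const std::string& s, std::vector<uint8_t>& out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = baseCode(s[i]);
    if (c < 0) throw std::runtime_error("sequence contains a non-ACGTN symbol");
    out[i] = static_cast<uint8_t>(c);
  }
}

inline bool scanForBmer(const uint8_t* s, int n, int b, uint64_t cand,
                        int& pos, int& orient) {
  if (n < b) return false;
  uint64_t crc = rcPacked(cand, b);
  uint64_t fwd = 0;
  int lastN = -1;
  for (int i = 0; i < n; ++i) {
    int c = s[i];
    if (c == 4) { lastN = i; c = 0; }
    fwd = ((fwd << 2) | static_cast<uint64_t>(c)) & kmask(b);
    if (i >= b - 1 && lastN < i - b + 1) {
      if (fwd == cand) { pos = i - b + 1; orient = 0; return true; }
      if (fwd == crc)  { pos = i - b + 1; orient = 1; return true; }
    }
  }
  return false;
}

inline uint32_t packPrefixCodes(const uint8_t* s, int p) {
  uint32_t v = 0;
  for (int i = 0; i < p; ++i) v = (v << 2) | s[i];
  return v;
}

// raw 4-line FASTQ footprint of a record, used for greedy block filling
inline size_t recordBytes(const std::string& id, const std::string& seq,
                          const std::string& qual) {
  return id.size() + seq.size() + qual.size() + 6;
}

struct CompressResult {
  std::vector<uint8_t> archive;
  std::vector<uint64_t> digests;      // state digest after each block
  uint64_t streamBytes[N_STREAMS] = {0, 0, 0, 0, 0, 0};
  uint64_t nBases = 0;
  uint64_t peHit = 0, peMiss = 0, nCorrections = 0;
  uint32_t nBlocks = 0;
};

class Compressor {
 public:
  Engine E;
  RangeEncoder rc[N_STREAMS];
  Fnv64 chk;
  bool firstInBlock = true;
  std::vector<uint8_t> orig1, work1, orig2, work2, qsyms;
  std::string expQualBuf;

  void startBlock() {
    for (int i = 0; i < N_STREAMS; ++i) rc[i] = RangeEncoder();
    E.base.blockReset();
    E.id.blockReset();
    chk = Fnv64();
    firstInBlock = true;
  }

  void encodeId(const std::string& id, int mate) {
    switch (E.P.idMode) {
      case IDMODE_LOSSLESS:
        E.id.encodeLossless(rc[ST_IDS], mate, id, firstInBlock);
        chk.add(id.data(), id.size());
        break;
      case IDMODE_INSTRUMENT: {
        E.id.encodeInstrument(rc[ST_IDS], id);
        std::string name = firstToken(id);
        chk.add(name.data(), name.size());
        break;
      }
      default: {  // discarded: decoder regenerates sequential placeholders
        std::string rid = "r" + std::to_string(E.unitCounter + 1);
        chk.add(rid.data(), rid.size());
      }
    }
    chk.u8(0);
  }

  void encodeQual(const std::string& qual) {
    int len = static_cast<int>(qual.size());
    if (E.P.qualMode == QMODE_NONE) {
      expQualBuf.assign(len, QUAL_PLACEHOLDER);
    } else {
      qsyms.resize(len);
      expQualBuf.resize(len);
      for (int i = 0; i < len; ++i) {
        int q = static_cast<unsigned char>(qual[i]) - 33;
        if (q < 0 || q >= QRANGE)
          throw std::runtime_error("quality character out of range [33,126]");
        qsyms[i] = E.P.qualSym[q];
        expQualBuf[i] = static_cast<char>(E.P.qualRep[qsyms[i]] + 33);
      }
      E.qual.encode(rc[ST_QUAL], qsyms.data(), len);
    }
    chk.add(expQualBuf.data(), expQualBuf.size());
    chk.u8(0);
  }

  // SE read, or first read of a pair
  void encodeRead1(const std::string& seq) {
    int len = static_cast<int>(seq.size());
    E.base.encodeLength(rc[ST_LEN], 0, len);
    seqToCodes(seq, orig1);
    work1.resize(len);
    int from = 0;
    if (E.P.reo) {
      int p = E.P.p;
      bool esc = len < p;
      if (!esc)
        for (int i = 0; i < p; ++i)
          if (orig1[i] == 4) { esc = true; break; }
      E.base.prefEscape.enc(rc[ST_PREF], esc ? 1 : 0);
      if (esc) {
        int m = len < p ? len : p;
        for (int i = 0; i < m; ++i)
          E.base.order0[i < 15 ? i : 15].enc(rc[ST_PREF], orig1[i]);
        from = m;
      } else {
        uint32_t cur = packPrefixCodes(orig1.data(), p);
        if (cur < E.base.prevPrefix)
          throw std::runtime_error(
              "internal error: REO prefixes not sorted (sorting contract violated)");
        encNumber(rc[ST_PREF], E.base.prefBits, cur - E.base.prevPrefix);
        E.base.prevPrefix = cur;
        from = p;
      }
    }
    E.base.codeReadBases<true>(&rc[ST_BASES], nullptr, orig1.data(),
                               work1.data(), len, from);
    E.base.dicts.insertRead(work1.data(), len);
    chk.add(seq.data(), seq.size());
    chk.u8(0);
  }

  // second read of a pair: minimizer-pair prediction with SE-style fallback
  void encodeRead2(const std::string& seq2, int len1) {
    int len2 = static_cast<int>(seq2.size());
    E.base.encodeLength(rc[ST_LEN], 1, len2);
    seqToCodes(seq2, orig2);
    work2.resize(len2);
    int L = E.P.b - 2;
    uint64_t m1 = 0;
    int m1pos = 0;
    bool haveM1 = findMinimizerPacked(orig1.data(), len1, L, m1, m1pos);
    MinimizerPairs::Entry* ent = haveM1 ? E.mb.find(m1) : nullptr;
    int hit = -1, hpos = -1, orient = 0;
    if (ent) {
      for (int r = 0; r < ent->n && hit < 0; ++r)
        if (scanForBmer(orig2.data(), len2, E.P.b, ent->m2[r], hpos, orient))
          hit = r;
    }
    E.peRank.enc(rc[ST_PE], hit < 0 ? MB_CAP : hit);
    int kf = -1, kt = -1;
    if (hit >= 0) {
      encNumber(rc[ST_PE], E.pePosBits, hpos);
      E.peOrient.enc(rc[ST_PE], orient);
      kf = hpos; kt = hpos + E.P.b;
      ++E.peHit;
    } else {
      ++E.peMiss;
    }
    E.base.codeReadBases<true>(&rc[ST_BASES], nullptr, orig2.data(),
                               work2.data(), len2, 0, kf, kt);
    E.base.dicts.insertRead(work2.data(), len2);
    if (haveM1) {
      uint64_t m2 = 0;
      int m2pos = 0;
      if (findMinimizerPacked(orig2.data(), len2, E.P.b, m2, m2pos))
        E.mb.record(m1, m2);
    }
    chk.add(seq2.data(), seq2.size());
    chk.u8(0);
  }
};

inline CompressResult compressRecords(
    const Params& P0,
    const std::vector<std::string>& id1, const std::vector<std::string>& seq1,
    const std::vector<std::string>& qual1,
    const std::vector<std::string>& id2, const std::vector<std::string>& seq2,
    const std::vector<std::string>& qual2) {
  Compressor C;
  C.E.P = P0;
  C.E.init();
  const Params& P = C.E.P;
  size_t n = seq1.size();

  // greedy block partition by raw FASTQ byte footprint
  std::vector<size_t> blockStart;
  {
    uint64_t cur = 0;
    for (size_t i = 0; i < n; ++i) {
      uint64_t sz = recordBytes(id1[i], seq1[i], qual1[i]);
      if (P.paired) sz += recordBytes(id2[i], seq2[i], qual2[i]);
      if (cur == 0 || cur + sz > P.blockSize) {
        blockStart.push_back(i);
        cur = 0;
      }
      cur += sz;
    }
  }

  CompressResult res;
  ByteWriter body;
  std::vector<uint32_t> blkUnits;
  std::vector<uint64_t> blkChk;
  std::vector<std::vector<uint32_t>> blkLens;

  for (size_t bi = 0; bi < blockStart.size(); ++bi) {
    size_t from = blockStart[bi];
    size_t to = (bi + 1 < blockStart.size()) ? blockStart[bi + 1] : n;
    C.startBlock();
    for (size_t i = from; i < to; ++i) {
      C.encodeRead1(seq1[i]);
      if (P.paired) C.encodeRead2(seq2[i], static_cast<int>(seq1[i].size()));
      C.encodeId(id1[i], 0);
      if (P.paired) C.encodeId(id2[i], 1);
      C.encodeQual(qual1[i]);
      if (P.paired) C.encodeQual(qual2[i]);
      res.nBases += seq1[i].size();
      if (P.paired) res.nBases += seq2[i].size();
      ++C.E.unitCounter;
      C.firstInBlock = false;
    }
    std::vector<uint32_t> lens(N_STREAMS, 0);
    for (int st = 0; st < N_STREAMS; ++st) {
      bool used = true;
      if (st == ST_PE && !P.paired) used = false;
      if (st == ST_PREF && !P.reo) used = false;
      if (st == ST_QUAL && P.qualMode == QMODE_NONE) used = false;
      if (st == ST_IDS && P.idMode == IDMODE_NONE) used = false;
      if (used) {
        C.rc[st].flush();
        lens[st] = static_cast<uint32_t>(C.rc[st].out.size());
        body.bytes(C.rc[st].out.data(), C.rc[st].out.size());
        res.streamBytes[st] += lens[st];
      }
    }
    blkUnits.push_back(static_cast<uint32_t>(to - from));
    blkChk.push_back(C.chk.h);
    blkLens.push_back(lens);
    res.digests.push_back(C.E.digest());
  }

  // header
  ByteWriter w;
  w.bytes(reinterpret_cast<const uint8_t*>(MAGIC), 4);
  w.u8(FORMAT_VERSION);
  w.u8(P.paired ? 1 : 0);
  w.u8(P.reo ? 1 : 0);
  w.u8(static_cast<uint8_t>(P.qualMode));
  w.u8(static_cast<uint8_t>(P.idMode));
  w.u64(P.genomeSize);
  w.u8(static_cast<uint8_t>(P.e));
  w.u8(static_cast<uint8_t>(P.p));
  w.u8(static_cast<uint8_t>(P.s));
  w.u8(static_cast<uint8_t>(P.b));
  w.u64(P.blockSize);
  w.u64(n);
  if (P.qualMode != QMODE_NONE) {
    w.u8(static_cast<uint8_t>(P.qualRep.size()));
    w.bytes(P.qualSym.data(), QRANGE);
    w.bytes(P.qualRep.data(), P.qualRep.size());
  } else {
    w.u8(0);
  }
  w.u32(static_cast<uint32_t>(blkUnits.size()));
  for (size_t i = 0; i < blkUnits.size(); ++i) {
    w.u32(blkUnits[i]);
    w.u64(blkChk[i]);
    for (int st = 0; st < N_STREAMS; ++st) w.u32(blkLens[i][st]);
  }
  w.v.insert(w.v.end(), body.v.begin(), body.v.end());
  res.archive = std::move(w.v);
  res.nBlocks = static_cast<uint32_t>(blkUnits.size());
  res.peHit = C.E.peHit;
  res.peMiss = C.E.peMiss;
  res.nCorrections = C.E.base.nCorrections;
  return res;
}

// ---------------------------------------------------------------------------

struct ArchiveHeader {
  Params P;
  uint64_t nUnits = 0;
  std::vector<uint32_t> blkUnits;
  std::vector<uint64_t> blkChk;
  std::vector<std::vector<uint32_t>> blkLens;
  size_t bodyOffset = 0;
};

inline ArchiveHeader readHeader(const uint8_t* a, size_t n) {
  ByteReader r(a, n);
  ArchiveHeader H;
  r.need(4);
  if (std::memcmp(a, MAGIC, 4) != 0)
    throw std::runtime_error("not an FQPK archive (bad magic bytes)");
  r.pos = 4;
  uint8_t ver = r.u8();
  if (ver != FORMAT_VERSION)
    throw std::runtime_error("unsupported FQPK format version");
  H.P.paired = r.u8() != 0;
  H.P.reo = r.u8() != 0;
  H.P.qualMode = r.u8();
  H.P.idMode = r.u8();
  H.P.genomeSize = r.u64();
  H.P.e = r.u8(); H.P.p = r.u8(); H.P.s = r.u8(); H.P.b = r.u8();
  H.P.blockSize = r.u64();
  H.nUnits = r.u64();
  uint8_t alpha = r.u8();
  if (H.P.qualMode != QMODE_NONE) {
    if (alpha == 0) throw std::runtime_error("corrupt archive: bad quality table");
    H.P.qualSym.resize(QRANGE);
    r.need(QRANGE);
    std::memcpy(H.P.qualSym.data(), a + r.pos, QRANGE);
    r.pos += QRANGE;
    H.P.qualRep.resize(alpha);
    r.need(alpha);
    std::memcpy(H.P.qualRep.data(), a + r.pos, alpha);
    r.pos += alpha;
  }
  uint32_t nb = r.u32();
  for (uint32_t i = 0; i < nb; ++i) {
    H.blkUnits.push_back(r.u32());
    H.blkChk.push_back(r.u64());
    std::vector<uint32_t> lens(N_STREAMS);
    for (int st = 0; st < N_STREAMS; ++st) lens[st] = r.u32();
    H.blkLens.push_back(lens);
  }
  H.bodyOffset = r.pos;
  return H;
}

struct DecompressResult {
  std::vector<std::string> id1, seq1, qual1, id2, seq2, qual2;
  std::vector<uint64_t> digests;
  bool paired = false;
};

inline DecompressResult decompressArchive(const uint8_t* a, size_t n) {
  ArchiveHeader H = readHeader(a, n);
  Engine E;
  E.P = H.P;
  E.init();
  const Params& P = E.P;

  DecompressResult res;
  res.paired = P.paired;
  res.id1.reserve(H.nUnits); res.seq1.reserve(H.nUnits);
  res.qual1.reserve(H.nUnits);
  if (P.paired) {
    res.id2.reserve(H.nUnits); res.seq2.reserve(H.nUnits);
    res.qual2.reserve(H.nUnits);
  }

  size_t off = H.bodyOffset;
  std::vector<uint8_t> orig1, work1, orig2, work2, qsyms;

  for (size_t bi = 0; bi < H.blkUnits.size(); ++bi) {
    RangeDecoder rd[N_STREAMS];
    for (int st = 0; st < N_STREAMS; ++st) {
      uint32_t len = H.blkLens[bi][st];
      if (off + len > n) throw std::runtime_error("truncated archive");
      if (len > 0) rd[st].init(a + off, len);
      off += len;
    }
    E.base.blockReset();
    E.id.blockReset();
    Fnv64 chk;

    for (uint32_t u = 0; u < H.blkUnits[bi]; ++u) {
      // --- first read ---
      int len1 = E.base.decodeLength(rd[ST_LEN], 0);
      orig1.resize(len1); work1.resize(len1);
      int from = 0;
      if (P.reo) {
        int p = P.p;
        int esc = E.base.prefEscape.dec(rd[ST_PREF]);
        if (esc) {
          int m = len1 < p ? len1 : p;
          for (int i = 0; i < m; ++i)
            orig1[i] = static_cast<uint8_t>(
                E.base.order0[i < 15 ? i : 15].dec(rd[ST_PREF]));
          from = m;
        } else {
          uint64_t delta = decNumber(rd[ST_PREF], E.base.prefBits);
          E.base.prevPrefix += static_cast<uint32_t>(delta);
          for (int i = 0; i < p; ++i)
            orig1[i] = static_cast<uint8_t>(
                (E.base.prevPrefix >> (2 * (p - 1 - i))) & 3);
          from = p;
        }
      }
      E.base.codeReadBases<false>(nullptr, &rd[ST_BASES], orig1.data(),
                                  work1.data(), len1, from);
      E.base.dicts.insertRead(work1.data(), len1);
      std::string s1(len1, 'A');
      for (int i = 0; i < len1; ++i) s1[i] = baseChar(orig1[i]);

      std::string s2;
      if (P.paired) {
        int len2 = E.base.decodeLength(rd[ST_LEN], 1);
        orig2.resize(len2); work2.resize(len2);
        int L = P.b - 2;
        uint64_t m1 = 0;
        int m1pos = 0;
        bool haveM1 = findMinimizerPacked(orig1.data(), len1, L, m1, m1pos);
        MinimizerPairs::Entry* ent = haveM1 ? E.mb.find(m1) : nullptr;
        int hit = E.peRank.dec(rd[ST_PE]);
        int kf = -1, kt = -1;
        if (hit < MB_CAP) {
          if (!ent || hit >= ent->n)
            throw std::runtime_error("corrupt archive: invalid pair candidate");
          int hpos = static_cast<int>(decNumber(rd[ST_PE], E.pePosBits));
          int orient = E.peOrient.dec(rd[ST_PE]);
          if (hpos < 0 || hpos + P.b > len2)
            throw std::runtime_error("corrupt archive: invalid pair position");
          uint64_t cand = ent->m2[hit];
          if (orient) cand = rcPacked(cand, P.b);
          for (int i = 0; i < P.b; ++i)
            orig2[hpos + i] = static_cast<uint8_t>(
                (cand >> (2 * (P.b - 1 - i))) & 3);
          kf = hpos; kt = hpos + P.b;
          ++E.peHit;
        } else {
          ++E.peMiss;
        }
        E.base.codeReadBases<false>(nullptr, &rd[ST_BASES], orig2.data(),
                                    work2.data(), len2, 0, kf, kt);
        E.base.dicts.insertRead(work2.data(), len2);
        if (haveM1) {
          uint64_t m2 = 0;
          int m2pos = 0;
          if (findMinimizerPacked(orig2.data(), len2, P.b, m2, m2pos))
            E.mb.record(m1, m2);
        }
        s2.assign(len2, 'A');
        for (int i = 0; i < len2; ++i) s2[i] = baseChar(orig2[i]);
      }

      // --- IDs ---
      std::string i1, i2;
      switch (P.idMode) {
        case IDMODE_LOSSLESS:
          i1 = E.id.decodeLossless(rd[ST_IDS], 0);
          if (P.paired) i2 = E.id.decodeLossless(rd[ST_IDS], 1);
          break;
        case IDMODE_INSTRUMENT:
          i1 = E.id.decodeInstrument(rd[ST_IDS]);
          if (P.paired) i2 = E.id.decodeInstrument(rd[ST_IDS]);
          break;
        default:
          i1 = "r" + std::to_string(E.unitCounter + 1);
          i2 = i1;
      }

      // --- qualities ---
      std::string q1, q2;
      auto decQual = [&](int len) {
        if (P.qualMode == QMODE_NONE)
          return std::string(static_cast<size_t>(len), QUAL_PLACEHOLDER);
        qsyms.resize(len);
        E.qual.decode(rd[ST_QUAL], qsyms.data(), len);
        std::string q(len, '!');
        for (int i = 0; i < len; ++i)
          q[i] = static_cast<char>(P.qualRep[qsyms[i]] + 33);
        return q;
      };
      q1 = decQual(len1);
      if (P.paired) q2 = decQual(static_cast<int>(s2.size()));

      chk.add(s1.data(), s1.size()); chk.u8(0);
      if (P.paired) { chk.add(s2.data(), s2.size()); chk.u8(0); }
      chk.add(i1.data(), i1.size()); chk.u8(0);
      if (P.paired) { chk.add(i2.data(), i2.size()); chk.u8(0); }
      chk.add(q1.data(), q1.size()); chk.u8(0);
      if (P.paired) { chk.add(q2.data(), q2.size()); chk.u8(0); }

      res.id1.push_back(std::move(i1));
      res.seq1.push_back(std::move(s1));
      res.qual1.push_back(std::move(q1));
      if (P.paired) {
        res.id2.push_back(std::move(i2));
        res.seq2.push_back(std::move(s2));
        res.qual2.push_back(std::move(q2));
      }
      ++E.unitCounter;
    }
    if (chk.h != H.blkChk[bi])
      throw std::runtime_error("corrupt archive: checksum mismatch in block " +
                               std::to_string(bi + 1));
    res.digests.push_back(E.digest());
  }
  return res;
}

}  // namespace fq

#endif
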