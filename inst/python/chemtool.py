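#!/usr/bin/env python
"""RDKit worker behind biochemlm's chemistry layer.

Reads one JSON request from stdin, writes one JSON response to stdout.
Request: {"op": <name>, ...op-specific fields...}

Ops
---
canonicalize: {"smiles": [..]}            -> {"result": [canonical or null, ..]}
heavy_atoms:  {"smiles": [..]}            -> {"result": [int or null, ..]}
morgan_fp:    {"smiles": [..], "nbits": 2048, "radius": 3}
                                          -> {"result": [[on-bit indices] or null, ..]}
sa_score:     {"smiles": [..]}            -> {"result": [float or null, ..]}
fragment:     {"smiles": [..], "max_cuts": 5, "rules": [SMARTS..]}
                                          -> {"result": [[{core, subs, core_heavy,
                                                sub_heavy}], ..]}
reassemble:   {"pairs": [{"core":.., "subs": [..]}, ..]}
                                          -> {"result": [smiles or null, ..]}

Attachment points are numbered atom-map dummies ([*:1].. [*:5]); map numbers
are assigned by the canonical atom ranking of the core so that identical cores
always carry identical labels. Heavy-atom counts exclude dummy atoms.
"""
import json
import sys
from itertools import combinations

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

DEFAULT_RULES = [
    "[C;$(C=O)]!@[N;!$(N=*)]",            # amide C-N
    "[C;$(C=O)]!@[O;X2;!$(O=*)]",         # ester C(=O)-O
    "[C;X4]!@[N;X3;!$(N=*);!$(N[C]=O)]",  # amine C-N (excluding amide N)
    "[C;X4]!@[O;X2;!$(O[C]=O)]",          # ether C-O (excluding ester O)
    "[c]!@[C;X4]",                        # aromatic C - sp3 C
    "[S;$(S(=O)(=O))]!@[N]",              # sulfonamide S-N
]


def _mol(smi):
    if smi is None:
        return None
    return Chem.MolFromSmiles(smi)


def op_canonicalize(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        out.append(Chem.MolToSmiles(m) if m is not None else None)
    return out


def _heavy(mol):
    return sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() > 1)


def op_heavy_atoms(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        out.append(_heavy(m) if m is not None else None)
    return out


def op_morgan_fp(req):
    nbits = int(req.get("nbits", 2048))
    radius = int(req.get("radius", 3))
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
        else:
            fp = AllChem.GetMorganFingerprintAsBitVect(m, radius, nBits=nbits)
            out.append(sorted(fp.GetOnBits()))
    return out


def op_sa_score(req):
    import os
    from rdkit.Chem import RDConfig
    sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
    import sascorer
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        out.append(sascorer.calculateScore(m) if m is not None else None)
    return out


def _eligible_bonds(mol, patterns):
    bonds = set()
    for p in patterns:
        for match in mol.GetSubstructMatches(p):
            a, b = match[0], match[-1]
            bd = mol.GetBondBetweenAtoms(a, b)
            if (bd is not None and bd.GetBondType() == Chem.BondType.SINGLE
                    and not bd.IsInRing()):
                bonds.add(bd.GetIdx())
    return sorted(bonds)


def _label_attachments(core, subs):
    """Replace isotope dummy labels with canonical atom-map numbers."""
    core = Chem.Mol(core)
    subs = [Chem.Mol(s) for s in subs]
    tmp = Chem.Mol(core)
    iso2pos = {}
    for a in tmp.GetAtoms():
        if a.GetAtomicNum() == 0:
            iso2pos[a.GetIsotope()] = a.GetIdx()
            a.SetIsotope(0)
    ranks = list(Chem.CanonicalRankAtoms(tmp, includeChirality=True))
    order = sorted(iso2pos, key=lambda iso: ranks[iso2pos[iso]])
    iso2map = {iso: i + 1 for i, iso in enumerate(order)}
    for m in [core] + subs:
        for a in m.GetAtoms():
            if a.GetAtomicNum() == 0:
                a.SetAtomMapNum(iso2map[a.GetIsotope()])
                a.SetIsotope(0)
    return Chem.MolToSmiles(core), [Chem.MolToSmiles(s) for s in subs]


def _fragment_one(smi, max_cuts, patterns):
    mol = _mol(smi)
    if mol is None:
        return None
    elig = _eligible_bonds(mol, patterns)
    results = []
    seen = set()
    for k in range(1, max_cuts + 1):
        for combo in combinations(elig, k):
            labels = [(i + 1, i + 1) for i in range(k)]
            try:
                frag = Chem.FragmentOnBonds(mol, list(combo), addDummies=True,
                                            dummyLabels=labels)
                pieces = Chem.GetMolFrags(frag, asMols=True, sanitizeFrags=True)
            except Exception:
                continue
            if len(pieces) != k + 1:
                continue
            ndum = [sum(1 for a in p.GetAtoms() if a.GetAtomicNum() == 0)
                    for p in pieces]
            # the core carries one attachment per cut, substituents exactly one
            core_idx = [0, 1] if k == 1 else [i for i, nd in enumerate(ndum)
                                              if nd == k]
            for ci in core_idx:
                if not all(ndum[i] == 1 for i in range(len(pieces)) if i != ci):
                    continue
                core = pieces[ci]
                subs = [pieces[i] for i in range(len(pieces)) if i != ci]
                try:
                    core_smi, sub_smis = _label_attachments(core, subs)
                except Exception:
                    continue
                key = (core_smi, tuple(sorted(sub_smis)))
                if key in seen:
                    continue
                seen.add(key)
                results.append({
                    "core": core_smi,
                    "subs": sub_smis,
                    "core_heavy": _heavy(core),
                    "sub_heavy": [_heavy(s) for s in subs],
                })
    return results


def op_fragment(req):
    max_cuts = int(req.get("max_cuts", 5))
    rules = req.get("rules") or DEFAULT_RULES
    patterns = [Chem.MolFromSmarts(s) for s in rules]
    if any(p is None for p in patterns):
        raise ValueError("invalid SMARTS in rule set")
    return [_fragment_one(smi, max_cuts, patterns) for smi in req["smiles"]]


def op_reassemble(req):
    out = []
    for pair in req["pairs"]:
        try:
            mol = _mol(pair["core"])
            for s in pair["subs"]:
                mol = Chem.CombineMols(mol, _mol(s))
            z = Chem.molzip(mol)
            Chem.SanitizeMol(z)
            out.append(Chem.MolToSmiles(z))
        except Exception:
            out.append(None)
    return out


OPS = {
    "canonicalize": op_canonicalize,
    "heavy_atoms": op_heavy_atoms,
    "morgan_fp": op_morgan_fp,
    "sa_score": op_sa_score,
    "fragment": op_fragment,
    "reassemble": op_reassemble,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"error": "unknown op: %s" % op}, sys.stdout)
        return 1
    try:
        result = OPS[op](req)
    except Exception as exc:  # reported to the R side as a structured error
        json.dump({"error": str(exc)}, sys.stdout)
        return 1
    json.dump({"result": result}, sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
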