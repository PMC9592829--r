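#!/usr/bin/env python
"""RDKit molecule backend.

Reads one JSON request object from stdin and writes one JSON response to
stdout.  Every op is batched over a list of SMILES so a single process
start amortizes the RDKit import cost.  Only JSON ever goes to stdout;
RDKit chatter is silenced.

Ops:
  ping         -> backend/RDKit version info
  standardize  -> largest organic fragment, neutralize, canonical SMILES
  props        -> molecular weight, Crippen AlogP
  scaffold     -> Bemis-Murcko scaffold canonical SMILES ("" if acyclic)
  fingerprints -> MACCS(166) / PubChem-style(881) / ErG(315) / Morgan(1024)
  graphs       -> heavy-atom graph with fixed atom/bond feature schema
  match        -> SMARTS substructure hits (molecules x patterns)
  depict       -> SVG depiction with atom/bond score highlighting
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, MACCSkeys, rdFingerprintGenerator
from rdkit.Chem import rdMolDescriptors, rdReducedGraphs
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

# ---------------------------------------------------------------------------
# PubChem-style 881-bit substructure keys.
#
# Layout follows the published PubChem fingerprint sectioning: hierarchic
# element counts, ring-size/composition counts over the SSSR, then bonded
# element pairs, atom neighbourhoods and short bonded chains expressed as
# SMARTS.  The SMARTS sections are generated combinatorially in a fixed,
# documented order (the verbatim published pattern strings are not
# reproduced); every bit is a real substructure test and the total is
# asserted to be 881.
# ---------------------------------------------------------------------------

_MULTI = [
    ("H", (4, 8, 16, 32)), ("Li", (1, 2)), ("Be", (1,)), ("B", (1, 2, 4)),
    ("C", (2, 4, 8, 16, 32)), ("N", (1, 2, 4, 8)), ("O", (1, 2, 4, 8, 16)),
    ("F", (1, 2, 4)), ("Na", (1, 2)), ("Mg", (1,)), ("Al", (1,)),
    ("Si", (1, 2)), ("P", (1, 2, 4)), ("S", (1, 2, 4, 8)),
    ("Cl", (1, 2, 4, 8)), ("K", (1, 2)), ("Ca", (1,)), ("Br", (1, 2, 4)),
    ("I", (1, 2, 4)),
]
_SINGLE = [
    "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge",
    "As", "Se", "Kr", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh",
    "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Te", "Xe", "Cs", "Ba", "La", "Ce",
    "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu",
    "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi",
    "Th", "U",
]


def element_count_defs():
    defs = [(sym, t) for sym, ts in _MULTI for t in ts]
    defs += [(sym, 1) for sym in _SINGLE]
    assert len(defs) == 115, len(defs)
    return defs


_RING_CLASSES = ["any", "carbon_only", "nitrogen", "hetero", "aromatic", "saturated"]
_RING_THRESH = {3: (1, 2), 4: (1, 2), 5: (1, 2, 3, 4, 5), 6: (1, 2, 3, 4, 5),
                7: (1, 2), 8: (1, 2), 9: (1,), 10: (1,)}


def ring_count_defs():
    # (size, class, threshold) triples + global ring statistics = 148 bits
    defs = [("size", sz, cls, t)
            for sz in sorted(_RING_THRESH)
            for t in _RING_THRESH[sz]
            for cls in _RING_CLASSES]
    defs += [("global", "aromatic_rings", None, t) for t in (1, 2, 3, 4)]
    defs += [("global", "hetero_aromatic_rings", None, t) for t in (1, 2, 3, 4)]
    defs += [("global", "rings", None, t) for t in range(1, 11)]
    defs += [("global", "fused_pairs", None, t) for t in (1, 2, 3, 4)]
    defs += [("global", "macrocycle", None, 1), ("global", "spiro", None, 1),
             ("global", "ring_assemblies", None, 2),
             ("global", "ring_assemblies", None, 3),
             ("global", "carbocycles", None, 2),
             ("global", "heterocycles", None, 2)]
    assert len(defs) == 148, len(defs)
    return defs


_NAMED_SMARTS = [
    "[CX3](=O)[OX2H1]",            # carboxylic acid
    "[CX3](=O)[O-]",               # carboxylate
    "[CX3](=O)[NX3]",              # amide
    "[CX3](=O)[OX2][#6]",          # ester
    "C#N",                         # nitrile
    "[NX3](=O)=O,[NX3+](=O)[O-]",  # (split below) placeholder
    "[SX4](=O)(=O)[NX3]",          # sulfonamide
    "[SX4](=O)(=O)[OX2]",          # sulfonate ester/acid
    "[OX2H]",                      # hydroxyl
    "[NX3;H2]",                    # primary amine
    "[NX3;H1][#6]",                # secondary amine
    "[nX2]",                       # basic aromatic nitrogen
    "[nH]",                        # pyrrole-type nitrogen
    "c1ccccc1",                    # benzene
    "c1ccncc1",                    # pyridine
    "o1cccc1",                     # furan
    "s1cccc1",                     # thiophene
    "[F,Cl,Br,I]c",                # halo-aromatic
    "[CX4][F,Cl,Br,I]",            # halo-aliphatic
    "O=[CX3]c",                    # aryl carbonyl
    "[OX2]([#6])[#6]",             # ether
    "[SX2]([#6])[#6]",             # thioether
    "C=C",                         # olefin
    "[CX3]=[NX2]",                 # imine
    "[#7]~[#7]",                   # N-N motif
]
_NAMED_SMARTS[5] = "[$([NX3](=O)=O),$([NX3+](=O)[O-])]"  # nitro, either form

_ARO = {"C": "c", "N": "n", "O": "o", "S": "s"}
_ATNUM = {"B": 5, "C": 6, "N": 7, "O": 8, "F": 9, "Si": 14, "P": 15,
          "S": 16, "Cl": 17, "Br": 35, "I": 53}


def _gen_pair_smarts():
    out = []
    els = ["B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"]
    for i, a in enumerate(els):
        for b in els[i:]:
            out.append("[#%d]-[#%d]" % (_ATNUM[a], _ATNUM[b]))
    dbl = ["C", "N", "O", "S", "P"]
    for i, a in enumerate(dbl):
        for b in dbl[i:]:
            out.append("[#%d]=[#%d]" % (_ATNUM[a], _ATNUM[b]))
    for a, b in (("C", "C"), ("C", "N"), ("N", "N")):
        out.append("[#%d]#[#%d]" % (_ATNUM[a], _ATNUM[b]))
    aro = ["C", "N", "O", "S"]
    for i, a in enumerate(aro):
        for b in aro[i:]:
            out.append("[%s]:[%s]" % (_ARO[a], _ARO[b]))
    return out


def _gen_neighbour_smarts():
    # central atom with two specified neighbours, any bond order
    out = []
    centers = ["C", "N", "O", "S", "P"]
    nbrs = ["C", "N", "O", "S", "F", "Cl", "Br"]
    for z in centers:
        for i, a in enumerate(nbrs):
            for b in nbrs[i:]:
                out.append("[#%d](~[#%d])~[#%d]"
                           % (_ATNUM[z], _ATNUM[a], _ATNUM[b]))
    # three specified neighbours around C/N/S/P centres
    tri = ["C", "N", "O"]
    for z in ["C", "N", "S", "P"]:
        for i, a in enumerate(tri):
            for j, b in enumerate(tri[i:], start=i):
                for c in tri[j:]:
                    out.append("[#%d](~[#%d])(~[#%d])~[#%d]"
                               % (_ATNUM[z], _ATNUM[a], _ATNUM[b], _ATNUM[c]))
    # aryl-attached two-bond chains
    for a in ["C", "N", "O", "S"]:
        for b in ["C", "N", "O", "S", "F", "Cl"]:
            out.append("[c]-[#%d]~[#%d]" % (_ATNUM[a], _ATNUM[b]))
    for a in ["C", "N", "O", "S"]:
        out.append("[n]:[c]-[#%d]" % _ATNUM[a])
    return out


_MAXVAL = {"C": 4, "N": 3, "O": 2, "S": 6, "P": 5}
_BOND_ORDER = {"-": 1, "=": 2, "#": 3}


def _gen_chain_smarts():
    # A b1 B b2 C bonded chains with a simple valence filter
    out = []
    els = ["C", "N", "O", "S"]
    bonds = ["-", "=", "#"]
    for a in els:
        for b1 in bonds:
            for b in els:
                for b2 in bonds:
                    for c in els:
                        if _BOND_ORDER[b1] > _MAXVAL[a]:
                            continue
                        if _BOND_ORDER[b2] > _MAXVAL[c]:
                            continue
                        if _BOND_ORDER[b1] + _BOND_ORDER[b2] > _MAXVAL[b]:
                            continue
                        out.append("[#%d]%s[#%d]%s[#%d]"
                                   % (_ATNUM[a], b1, _ATNUM[b], b2, _ATNUM[c]))
    return out


def _gen_aryl_smarts():
    out = []
    for x in ["#6", "#7", "#8", "#9", "#16", "#17", "#35", "#53", "#15"]:
        out.append("[c]-[%s]" % x)
    for x in ["n", "o", "s"]:
        out.append("[c]:[%s]:[c]" % x)
    out += ["c1ccc2ccccc2c1", "c1ccc2ncccc2c1", "c1ccc2[nH]ccc2c1",
            "C1CCCCC1", "C1CCCC1", "C1CCNCC1", "C1CCOCC1", "C1CCNC1"]
    return out


def pubchem_style_smarts():
    pats = list(_NAMED_SMARTS)
    pats += _gen_pair_smarts()
    pats += _gen_neighbour_smarts()
    pats += _gen_chain_smarts()
    pats += _gen_aryl_smarts()
    # de-duplicate preserving order, then cut to exactly 618 slots
    seen, uniq = set(), []
    for p in pats:
        if p not in seen:
            seen.add(p)
            uniq.append(p)
    assert len(uniq) >= 618, len(uniq)
    return uniq[:618]


_PUBCHEM_CACHE = {}


def _pubchem_patterns():
    if "pats" not in _PUBCHEM_CACHE:
        _PUBCHEM_CACHE["pats"] = [Chem.MolFromSmarts(s)
                                  for s in pubchem_style_smarts()]
        assert all(p is not None for p in _PUBCHEM_CACHE["pats"])
    return _PUBCHEM_CACHE["pats"]


def _ring_profile(mol):
    ri = mol.GetRingInfo()
    rings = []
    for atoms in ri.AtomRings():
        syms = [mol.GetAtomWithIdx(i).GetSymbol() for i in atoms]
        arom = all(mol.GetAtomWithIdx(i).GetIsAromatic() for i in atoms)
        bonds = ri.BondRings()[len(rings)]
        sat = all(mol.GetBondWithIdx(b).GetBondType() == Chem.BondType.SINGLE
                  for b in bonds)
        rings.append({
            "size": len(atoms),
            "carbon_only": all(s == "C" for s in syms),
            "nitrogen": "N" in syms,
            "hetero": any(s != "C" for s in syms),
            "aromatic": arom,
            "saturated": sat,
            "atoms": set(atoms),
        })
    return rings


def pubchem_style_fp(mol):
    bits = []
    counts = {}
    for atom in mol.GetAtoms():
        counts[atom.GetSymbol()] = counts.get(atom.GetSymbol(), 0) + 1
        counts["H"] = counts.get("H", 0) + atom.GetTotalNumHs()
    for sym, t in element_count_defs():
        bits.append(1 if counts.get(sym, 0) >= t else 0)

    rings = _ring_profile(mol)
    n_fused = sum(1 for i in range(len(rings)) for j in range(i + 1, len(rings))
                  if len(rings[i]["atoms"] & rings[j]["atoms"]) >= 2)
    n_spiro = sum(1 for i in range(len(rings)) for j in range(i + 1, len(rings))
                  if len(rings[i]["atoms"] & rings[j]["atoms"]) == 1)
    glob = {
        "aromatic_rings": sum(r["aromatic"] for r in rings),
        "hetero_aromatic_rings": sum(r["aromatic"] and r["hetero"] for r in rings),
        "rings": len(rings),
        "fused_pairs": n_fused,
        "macrocycle": sum(r["size"] > 10 for r in rings),
        "spiro": n_spiro,
        "ring_assemblies": len(rings),
        "carbocycles": sum(r["carbon_only"] for r in rings),
        "heterocycles": sum(r["hetero"] for r in rings),
    }
    for kind, a, cls, t in ring_count_defs():
        if kind == "size":
            n = sum(1 for r in rings
                    if r["size"] == a and (cls == "any" or r[cls]))
            bits.append(1 if n >= t else 0)
        else:
            bits.append(1 if glob[a] >= t else 0)

    for pat in _pubchem_patterns():
        bits.append(1 if mol.HasSubstructMatch(pat) else 0)
    assert len(bits) == 881
    return bits


# ---------------------------------------------------------------------------
# Standardization: largest organic fragment + charge neutralization
# ---------------------------------------------------------------------------

_FRAGMENT = rdMolStandardize.LargestFragmentChooser(preferOrganic=True)
_UNCHARGE = rdMolStandardize.Uncharger()


def standardize_one(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "error": "unparseable SMILES"}
    try:
        mol = rdMolStandardize.Cleanup(mol)
        mol = _FRAGMENT.choose(mol)
        mol = _UNCHARGE.uncharge(mol)
        Chem.SanitizeMol(mol)
    except Exception as e:  # pragma: no cover - rare sanitization failures
        return {"ok": False, "error": str(e)}
    return {"ok": True, "smiles": Chem.MolToSmiles(mol)}


# ---------------------------------------------------------------------------
# Graph featurization (heavy atoms, fixed schema)
# ---------------------------------------------------------------------------

_ELEMENTS = ["C", "N", "O", "S", "F", "Cl", "Br", "I", "P"]  # + other
_HYBRID = [Chem.HybridizationType.SP, Chem.HybridizationType.SP2,
           Chem.HybridizationType.SP3]                        # + other
ATOM_FDIM = len(_ELEMENTS) + 1 + 6 + 1 + 1 + 5 + len(_HYBRID) + 1 + 1
BOND_FDIM = 4 + 1 + 1


def _onehot(x, choices):
    v = [0] * (len(choices) + 1)
    v[choices.index(x) if x in choices else len(choices)] = 1
    return v


def atom_features(atom):
    f = _onehot(atom.GetSymbol(), _ELEMENTS)
    deg = min(atom.GetDegree(), 5)
    f += [1 if i == deg else 0 for i in range(6)]
    f += [atom.GetFormalCharge(), 1 if atom.GetIsAromatic() else 0]
    nh = min(atom.GetTotalNumHs(), 4)
    f += [1 if i == nh else 0 for i in range(5)]
    f += _onehot(atom.GetHybridization(), _HYBRID)
    f += [1 if atom.IsInRing() else 0]
    return f


def bond_features(bond):
    bt = bond.GetBondType()
    f = [1 if bt == t else 0 for t in
         (Chem.BondType.SINGLE, Chem.BondType.DOUBLE,
          Chem.BondType.TRIPLE, Chem.BondType.AROMATIC)]
    f += [1 if bond.GetIsConjugated() else 0, 1 if bond.IsInRing() else 0]
    return f


def graph_one(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None or mol.GetNumAtoms() == 0:
        return {"ok": False, "error": "unparseable or empty molecule"}
    af = [atom_features(a) for a in mol.GetAtoms()]
    edges, bf = [], []
    for b in mol.GetBonds():
        i, j = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
        feats = bond_features(b)
        edges += [[i, j], [j, i]]
        bf += [feats, feats]
    return {"ok": True, "n_atoms": mol.GetNumAtoms(),
            "atom_features": af, "edges": edges, "bond_features": bf}


# ---------------------------------------------------------------------------
# Fingerprints
# ---------------------------------------------------------------------------

_MORGAN = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=1024)


def _bitstring(bits):
    return "".join("1" if b else "0" for b in bits)


def fingerprints(smiles, kinds):
    out = {k: [] for k in kinds}
    for smi in smiles:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            for k in kinds:
                out[k].append(None)
            continue
        if "maccs" in kinds:
            mk = MACCSkeys.GenMACCSKeys(mol)       # 167 bits, bit 0 unused
            out["maccs"].append(_bitstring([mk[i] for i in range(1, 167)]))
        if "pubchem" in kinds:
            out["pubchem"].append(_bitstring(pubchem_style_fp(mol)))
        if "morgan" in kinds:
            fp = _MORGAN.GetFingerprint(mol)
            out["morgan"].append(_bitstring([fp[i] for i in range(1024)]))
        if "erg" in kinds:
            erg = rdReducedGraphs.GetErGFingerprint(mol)
            out["erg"].append([round(float(x), 5) for x in erg])
    return out


# ---------------------------------------------------------------------------
# Depiction
# ---------------------------------------------------------------------------

def depict(smi, atom_scores, path):
    from rdkit.Chem.Draw import rdMolDraw2D
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "error": "unparseable SMILES"}
    n = mol.GetNumAtoms()
    if isinstance(atom_scores, dict):  # named vectors serialize as objects
        atom_scores = [atom_scores[k]
                       for k in sorted(atom_scores, key=int)]
    flat = [float(x[0]) if isinstance(x, (list, tuple)) else float(x)
            for x in atom_scores]
    scores = flat[:n] + [0.0] * max(0, n - len(flat))
    acol = {i: (1.0, 1.0 - 0.85 * s, 1.0 - 0.85 * s)
            for i, s in enumerate(scores)}
    bcol, bids = {}, []
    for b in mol.GetBonds():
        s = 0.5 * (scores[b.GetBeginAtomIdx()] + scores[b.GetEndAtomIdx()])
        bids.append(b.GetIdx())
        bcol[b.GetIdx()] = (1.0, 1.0 - 0.85 * s, 1.0 - 0.85 * s)
    d = rdMolDraw2D.MolDraw2DSVG(420, 360)
    rdMolDraw2D.PrepareAndDrawMolecule(
        d, mol, highlightAtoms=list(range(n)), highlightAtomColors=acol,
        highlightBonds=bids, highlightBondColors=bcol)
    d.FinishDrawing()
    with open(path, "w") as fh:
        fh.write(d.GetDrawingText())
    return {"ok": True, "path": path}


# ---------------------------------------------------------------------------
# Dispatch
# ---------------------------------------------------------------------------

def main():
    req = json.load(sys.stdin)
    op = req["op"]
    if op == "ping":
        import rdkit
        res = {"ok": True, "rdkit": rdkit.__version__,
               "atom_fdim": ATOM_FDIM, "bond_fdim": BOND_FDIM}
    elif op == "standardize":
        res = {"ok": True, "results": [standardize_one(s) for s in req["smiles"]]}
    elif op == "props":
        vals = []
        for s in req["smiles"]:
            mol = Chem.MolFromSmiles(s)
            if mol is None:
                vals.append(None)
            else:
                vals.append({"mw": round(Descriptors.MolWt(mol), 4),
                             "alogp": round(Crippen.MolLogP(mol), 4)})
        res = {"ok": True, "results": vals}
    elif op == "scaffold":
        vals = []
        for s in req["smiles"]:
            mol = Chem.MolFromSmiles(s)
            if mol is None:
                vals.append(None)
            else:
                sc = MurckoScaffold.GetScaffoldForMol(mol)
                vals.append(Chem.MolToSmiles(sc) if sc.GetNumAtoms() else "")
        res = {"ok": True, "results": vals}
    elif op == "fingerprints":
        res = {"ok": True,
               "results": fingerprints(req["smiles"], req["kinds"])}
    elif op == "graphs":
        res = {"ok": True, "results": [graph_one(s) for s in req["smiles"]],
               "atom_fdim": ATOM_FDIM, "bond_fdim": BOND_FDIM}
    elif op == "match":
        pats = [Chem.MolFromSmarts(p) for p in req["smarts"]]
        if any(p is None for p in pats):
            bad = [req["smarts"][i] for i, p in enumerate(pats) if p is None]
            res = {"ok": False, "error": "invalid SMARTS: %s" % ", ".join(bad)}
        else:
            rows = []
            for s in req["smiles"]:
                mol = Chem.MolFromSmiles(s)
                if mol is None:
                    rows.append(None)
                else:
                    rows.append(_bitstring(
                        [mol.HasSubstructMatch(p) for p in pats]))
            res = {"ok": True, "results": rows}
    elif op == "match_atoms":
        pat = Chem.MolFromSmarts(req["smarts"])
        if pat is None:
            res = {"ok": False, "error": "invalid SMARTS"}
        else:
            rows = []
            for s in req["smiles"]:
                mol = Chem.MolFromSmiles(s)
                if mol is None:
                    rows.append(None)
                else:
                    hits = mol.GetSubstructMatches(pat)
                    rows.append(sorted({i for h in hits for i in h}))
            res = {"ok": True, "results": rows}
    elif op == "depict":
        res = depict(req["smiles"], req.get("atom_scores", []), req["path"])
    else:
        res = {"ok": False, "error": "unknown op: %s" % op}
    json.dump(res, sys.stdout)
    sys.stdout.write("\n")


if __name__ == "__main__":
    main()
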