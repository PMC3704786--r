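>synEctC_1
HGDARGNFEKDPKADSDKYAGWRPSFQCENHIISQYEIFKLESFRHTKAIHHLSELIPGDFSGNWVSRCNPLNHRTMWNKMIGFTTGSMAGGCKSNLEDGPQGQDMTQLLLYAFNLRGYIEIVQTCVKRI
>synEctC_2
DGDARGNFEDDPKADEQKYWGPLPSVQCQNWIISGLEIFCLEMFGHSKDSKILSPLYPEDFSGNVVNRCNPLNVRTGWGHCIWSTTGSKAPGGKSNLSNLLQGQNPGQYLQYAMNLRTYLTSVQTCVNYI
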