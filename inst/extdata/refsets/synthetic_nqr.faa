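>synNqrA
FRVDIELNVQQTVVFEQPKDIYVDLEQGMPAWWDLWWLLFQHLVMLSAHTPYLFIWEVDLKSLGIIDSRTIAKMLLCLKDQRDATALVISRLIAKDDLPSDNDRIRKFVLLFHSNLYITRVFQGEGLELTRRTKIQEDKGASKFIGTQLFLSGYLLMETNGFMPLAVSGIRNIAQPLVKGLTHRTAVTARPSDMTGKIVLTTEPKQQLGGPLHSVIPLASLYVSEESSIPEVVSYRALSVISLGGEVTAYHGQTSVEHLVSGEELGNPGVHKVSKNGTPAADTKKAPLDVILMNILQSLLFISNCQAHGEKPGRALVPVTIAPIPARNLEKTEWEFLTKEAKGQAAVNEGLSIDHGEFLMAKGFYEMFSATCPFNHKDEWIIVEVRDLPVAIFRVKGDDSEENSNSTYGIGKQYSGLEPLEGMGVEGKAAHVRIETTERDYLVSKR
>synNqrB
DNSAQDKPNINPGRHTVFIRGLVLGDEAMPLQDDNQMAMPNTKYWITGEHFYVDSIDEEVMQGVKCGDGCIADRSAEDILEAMSHYDLMDEEPFYIPAFMRSIFREGPRQTAQATPNKETGKKLGKIECAQQLFESVVMGVGKVVGQQGAECPHATKVLPPQANEGLVKESCQMSYGVRCKVRTENNFLAGSLDCTCSAMTHSPLSDSNAATTIDLKCPLPEVPEEGLCTASTVGHGQEWIETYYKLGTCALTIDIQVLYIARSLVPTPGEEGRTTNALALLWVSKKETMAPEPYGNGVDPNMAPVRQSGNAYVESLLIILAHVLEISVFTQVMKQRVIATAGDKLPESICNILDYLKPEDAHDLCPCKLLSNATDFTSLQKRSGPRKPLMWNRPYAEFLHLLGIHASQDFNALY
>synNqrC
VCADNSDDALNMHVQCDRSAIIGEPMLGLAVFSCREKFNAYIARFKVPIMDIPTNEKLPATSCDSLPLKDYAGSFRSIAYRLHELMLVVRDTKGEPISLSKDKIGRAKYRVGRGNGPLKYDFQQLYAKCNAGWPLRDLSEPDEYRNKKKALGHSPGAISFTMDYQLQLDAPLDKLIRILCQIQCEFPPYEPRDFNNDHPIDKYERTHRSAYDESQGDKLLSLRVARSADESREAPTPSPADFADRWSWTKKRKTMAD
>synNqrD
TASPLSGNAKGKQPFGQSFKELAAAIFDRFTSVVTEEKIAKDPKAPHPVEHLGQVIYRCGRICLVKKAHKMNQDATTQAEMVGIETVPPSVEKATDKAHGGNALPSISHPKPARKLDERIVTKAPLFCIGNLASLMGDWVIDEAPVSDKSSPKRMEVANKIILVSREGVFKCAPFGNDQDDVKRETYIGNAWDAKFCGLSQKHGENCSVE
>synNqrE
QLHHSQDGLWARLGSQFYIPAFAKKKTFFYASVVVKCVELDRGIVVLEVERDTTEADSCDTITGNGITTMSGTSLQKGDERPYADKMRTAGIGPGLKIIILMLDIRGALSEALVAYKRDKLRESSRDYYAEDVFDKKHFAVYNTAPYIAKDPRVTGLNLTYSNLALMPALDAAAGYIISYIQTSNATCADQVGCVNSS
>synNqrF
RRVTKSDGCYINKDKRGFFTSKAQRWEYFKAAVFAEQQGRLAEKISSLMTMLARSRERGGVQGGDIISPVMKKEIAVKMPANFLNKPDPRSPPNPIPEKRRVPSECPFGTPTINPMDATFNDVGATQEETFGTAERSSIMPGNRKTGPIWDSTITVSKTHTSIKQDTERRADVYRYIMNLIECGALVCSNLQDETVMRLGEAEDITFKYIHPLPNRDLATAPPSEAPPGTANKQYDLGTQLIFMILQCSHGRKVKTFTDCLKRPLGRLPGKVEQGAEVDFVALIELLCGEDLVPFVESRGVALQPGNAVAGLPESIALSPEETTPAIWKFKKSNTETSLLLGQVNEVSKSLHQELNAGPMKPVCLGLSRSFEQAMEEVLWNAKYVSGAVLLLGSTYVEGRHSHGSEFD
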