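>synEctB_1
LQLEETMAGKAELVHYAEFGNPKVHSNEQLLGNPHIVCQMFKKLGMYWDAQEAGRINMCWEMVMYECPVTELTTITTLVCRIQILESTSPKLVSDLKEVVLNEFPPGAQKKRFRILDFGRMESWILLPAELFGRGLLHWIPEFHDRIGCVQANPVRMGSILVDTPIPLIIALYPSCVQGAACLIALLAGYLVIQDYHCKVEPMSINVCSVAIISNALRPVPGPKQKAIKKDGSAEPGAPLIAWHVLQELIGVYKKALIAKGIEAASDEWDTSNKDRWHFSWTSLGGTYFAAHAGIDPQRV
>synEctB_2
LQEYETCAGFAELVWFADFGNPKVHSTESLLGYPWTCCRYSGKLQSYWDQQTAGGINECMEAVMYECPVTELTTITTLKLMIQILESTSPKLVSDLISLQLNHPPGGASKKRFNILGFGDLETMILLPEELFGDGLVHWILEQHDRIGIVQAGPVRRGSILVDTPIPLIAALYGSCVQGRACYRAGLFGPLVIQDYQVKVEVHSINVMSVDIISNTLRPVFWPKQCAIKKDGSACRGAPLWAWECLQFGIGRLKKLLIASGISAASDSWDTSRQDRWHQSYTNLGGTAYATMCGIDWARV
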