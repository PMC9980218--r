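>Nbenthamiana_IPI1_syn
SAKNIRQMVDDHWVFDFAEWEQCGFKSAFQEPVPETMKHNGVYQGENLQLWMDPPLWDNW
>Ntabacum_syn
SAKNIRQMVLDHWVFDFAEWEQCGFKSAFQEPWPETMKHNGVYQGENLQLWMDPPLWDNW
>Slycopersicum_syn
SAKNIRQMVDDHWVFDYAEWEQCGFKSAFQEPVPETMDHNGVYQGENLQLWMDPPLDDNW
>Athaliana_syn
SAKNIRQMVDDHWVFDCAEWEQCGFKKAFQEPVPETMKWNGVYQGENLQSWMDPPLPDLW
>Gmax_syn
SAKNIRQMVDIHWVIDFAEWEQCGFKSAFQEPVPETMYHNGVYQGENLQLWMDPPLCDNW
>Zmays_PPR103_syn
SAKESRQVVDDHWVGDWAEWKQCGFKSTFQELVPGVQKYNGVYQGENLQLWMNPPTW---
>Osativa_syn
SAKESRQVVDDHWVGDWAEWKQCGFKSTFQELVPGVQKYNGVYQGENLQTWMCPPTW---
>Sbicolor_syn
SAKESRQVVDDHWVGDWAEWKQCGFKSTFQELVPGVQKYNGVYQGENLQMWNNPPTW---
>Taestivum_syn
SAKESRQVVDDHWVGDWAEWIQCGFKSTFQEQVPGVQKYNGLYQGENLQLWMNPPTW---
>Ppatens_syn
SAKNIRQMHDDHWVSDFAEAEQHGIKSAFQEPVPEMMKPGSCYQGENLQLYGDPPLWDYW
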