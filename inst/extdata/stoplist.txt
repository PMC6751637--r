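# Default common-word stoplist for dictionary refinement.
# Standard English stopwords plus geographic and common words that are
# known to collide with taxon or disease labels. One word per line;
# matching is case-insensitive. Edit or replace via the stoplist option.
the
and
for
are
but
not
you
all
any
can
her
was
one
our
out
day
get
has
him
his
how
man
new
now
old
see
two
way
who
boy
did
its
let
put
say
she
too
use
that
with
have
this
will
your
from
they
know
want
been
good
much
some
time
very
when
come
here
just
like
long
make
many
more
most
only
over
such
take
than
them
well
were
what
about
after
again
below
could
every
first
found
great
house
large
learn
never
other
place
plant
point
right
small
sound
spell
still
study
their
there
these
thing
think
three
water
where
which
world
would
write
cell
cells
data
group
groups
case
cases
control
controls
level
levels
line
lines
major
minor
model
name
names
rate
rates
result
results
type
types
value
values
# geographic / proper-noun collisions
arabia
katanga
africa
america
asia
europe
china
india
congo
kenya
niger
chad
cuba
peru
chile
japan
spain
france
brazil
mexico
egypt
sudan
mali
togo
iran
iraq
texas
paris
berlin
geneva
victoria
# common words seen as taxon synonyms
cancer
camel
horse
mouse
sheep
goat
chicken
turkey
salmon
bass
carp
crane
robin
swift
iris
aster
cedar
maple
cotton
rice
wheat
onion
grape
pepper
ginger
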